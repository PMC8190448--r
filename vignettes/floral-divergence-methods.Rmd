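---
title: "Methods: community assembly and macroevolution of floral traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community assembly and macroevolution of floral traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floradiverge)
```

## The scientific question

When many close relatives of a plant radiation coexist, their flowers may
diverge for three quite different reasons: divergence may be part of the
speciation process itself (a *speciational* model, in which phenotypic change
is concentrated at lineage-splitting events); it may accumulate gradually in
allopatry through drift or local adaptation (an *allopatric divergence*
model, i.e. Brownian motion); or it may be driven by negative interactions —
competition for pollinators, reproductive interference — among species that
meet in sympatry (a *negative interactions* model, in which the rate of
phenotypic change grows with standing diversity). The three models leave
different fingerprints in (i) the floral trait structure of present-day
communities, (ii) phylogenetic signal and the tempo of trait disparity, and
(iii) the relationship between branch-specific rates of trait evolution and
of lineage diversification.

`floradiverge` implements the full chain of analyses needed to read those
fingerprints from four inputs: a dated phylogeny, a site-by-species incidence
survey with coordinates, a per-species flowering/morphology table, and an
organ-weighted flower colour table extracted from photographs. A seeded
synthetic-data module generates all four inputs under each of the three
models, so every stage of the pipeline is testable without field data.

## Colour profiles and earth-mover distances

An inflorescence is not one colour: each floral organ (perianth, pistil,
pollen presenter, ...) contributes its own RGB centroid and a share of the
total colour signal. A species is therefore a *weighted point set* in the RGB
unit cube, and the chromatic distance between two species is the earth-mover
(transportation) distance between their point sets under Euclidean ground
distance: the minimal cost of rearranging one species' colour mass into the
other's. This respects both hue differences and how much of the display each
colour occupies.

Because profiles carry at most a handful of organ centroids, we solve the
transportation problem exactly with a transportation simplex
(north-west-corner start, u–v duals, cycle pivots). Degeneracy is broken by
an epsilon perturbation of the supplies; flows on the optimal basis are then
re-solved against the unperturbed margins, so returned costs are exact to
machine precision (the test suite demands 1e-8 agreement with an independent
LP oracle). We deliberately keep point sets rather than binned histograms —
binning one centroid per organ would only blur — and we stay in RGB rather
than a perceptual space, since the photographic pipeline the package mirrors
worked in RGB.

Downstream analyses consume the pairwise distance matrix through classical
principal-coordinate analysis (`pcoa_embed`, default `k = 5` axes). Negative
eigenvalues, which a non-Euclidean distance matrix can produce, are truncated
to zero with a warning; variance-explained fractions are taken over the
positive spectrum.

## Flowering phenology on the circle

Calendar months map to angles (month *m* at `2*pi*(m-1)/12`), and each
species contributes one angle: the circular mean of its months in flower,
which keeps wrap-around periods (November–February) honest. The choice of
one angle per species (rather than one per species-month) matches a
species-level, monthly-resolution survey; the Rayleigh statistic reported is
the mean resultant length `rbar` in [0, 1], with the standard large-sample
p-value approximation. Pairwise phenological overlap is the proportion of
the shorter flowering period shared with the longer; geographic overlap is
the fraction of the smaller-ranged species' occurrence sites lying within a
radius (default 20 km) of the larger-ranged species' occurrences — a
pragmatic stand-in for range polygons, which surveys rarely provide.
Coordinates are treated as planar km throughout: the target study regions
are small, and the dispersal kernel only needs monotone distances.

## Community assembly: FRic, MPD and two null models

Functional richness (FRic) of a community is the convex-hull volume of its
species in trait space divided by the hull volume of the whole species pool;
for pistil length this is a range ratio, for colour the hull is taken in the
leading `min(k, richness - 1)` PCoA axes (standard FRic practice for small
communities, whose points cannot span more dimensions). Sites need more than
two species for FRic and at least two for MPD (mean pairwise patristic
distance); sites with coincident trait points score FRic 0 rather than being
dropped. The regional test statistic is the *mean over eligible sites*, not
per-site standardized effects.

Hull volumes have no qhull binding available in this environment, so they
are computed exactly in-package: range in 1-D, shoelace area in 2-D, simplex
determinants for d+1 points, and brute-force supporting-hyperplane
enumeration with centroid-pyramid accumulation otherwise. A deterministic
1e-9 relative jitter (simulation of simplicity) breaks coplanarity ties; the
induced error is of the same order and is immaterial against the statistical
use of the volumes. The implementation is cross-checked against scipy's
qhull in the tests.

Observed regional means are compared to 1000 (configurable) randomized
assemblages under two null models:

* **Independent swap** — repeated 2x2 checkerboard submatrix swaps, which
  preserve every site's richness and every species' occurrence frequency
  exactly. We run a single swap chain (vegan's compiled implementation)
  with a burn-in of 1000 swaps per matrix occurrence and thinning of one
  occurrence-count between saved replicates; both knobs are exposed, and the
  calibration tests scale them down for runtime.
* **Dispersal null** — each site redraws its observed richness without
  replacement, species weighted by `sum(exp(-decay * d))` over that
  species' other occurrences. The source description fixes no decay
  rate; we default to 1 / (mean pairwise inter-site distance) and expose it.
  Sites where every weight vanishes fall back to frequency-proportional
  draws.

Verdicts are two-sided: an observed mean below the empirical 2.5% quantile
of the null means is "below", above the 97.5% quantile "above", otherwise
"within". Under its own generator the test holds a ~5% false-positive rate
(checked at 800 replicate worlds), and the divergence-filter generator is
detected as "above" essentially always.

## Phylogenetic signal and the tempo of disparity

Blomberg's K is the observed ratio of mean squared error around the
phylogenetic (GLS) mean to the phylogenetically corrected mean squared
error, scaled by its analytic Brownian expectation, so K = 1 under Brownian
motion; its p-value comes from 999 tip permutations (seeded, observed
included in the reference set). Pagel's lambda multiplies the off-diagonal
phylogenetic covariance and is ML-estimated on [0, 1], with a chi-square(1)
likelihood-ratio test against lambda = 0; at lambda = 0 the likelihood
provably equals the white-noise likelihood, which the tests assert. Both
statistics are affine-invariant.

Trait-evolution mode is compared across Brownian motion (2 parameters),
single-optimum Ornstein–Uhlenbeck with the optimum at the root state (3
parameters; the standard generic-OU choice for this BM/OU/WN trio) and white
noise (2 parameters), ranked by small-sample AICc and Akaike weights. The
OU likelihood is profiled analytically in rate and root, leaving a 1-D
search over `alpha`; as `alpha -> 0` it recovers the BM likelihood.

Disparity through time follows the classic subclade-disparity construction:
disparity is the mean squared pairwise trait distance among a clade's tips;
at each internal-node height (root first, where the relative disparity is 1
by construction) the curve records the mean relative disparity of the
lineages crossing that time. The observed curve is compared to a pointwise
95% envelope from 1000 multivariate Brownian simulations whose rate matrix
is estimated from the phylogenetic independent contrasts of the data. All
embedding axes enter the distance unweighted — the source analyses do not
state a weighting, and the PCoA axes already carry their eigenvalue scale.
The MDI statistic (mean deviation from the simulation mean) is reported
descriptively, without a test, since envelopes are the inferential device
here. Lineage-through-time curves come with the constant-rate expectation,
log-linear between 2 lineages at the root divergence and n at present.

## Branch-specific rates and the rate regression

Per-branch trait rates come from phylogenetic ridge regression: tip values
(centred on the GLS root estimate) are decomposed into per-edge changes
`delta` minimising `||x0 - A delta||^2 + penalty * ||delta||^2`, where `A`
is the root-to-tip path incidence matrix; the branch rate is
`|delta|/length`. The ridge penalty is chosen by generalized
cross-validation over a fixed log grid (1e-4 to 1e4, 25 points) — the
source method's tuning is unspecified, and GCV is the standard seed-free
choice; `penalty = 0` gives the minimum-norm least-squares solution, which
the tests pin against a dense LS oracle. Colour rates use the species'
dominant colour (the organ with the largest signal share, ties broken by
organ name).

Branch-specific diversification rates are deliberately *not* estimated by a
Bayesian diversification model (out of scope here): the default proxy is the
inverse equal-splits (DR) statistic averaged over an edge's descendant tips,
behind an interface that accepts any externally computed per-edge rates, so
published MCMC estimates can be injected unchanged. The DR proxy scales
inversely with branch lengths and is label-order invariant.

The regression couples `log(trait_rate + 0.1)` to standardized
`log(div_rate + 0.1)` and branch age (the child node's distance from the
root — large values are *recent* branches). Whether age should also be
log-transformed is ambiguous in the source description; we standardize it
untransformed by default and expose `log_age`. Each branch's random effect
lives at its child node, with covariance proportional to shared root-to-node
path length — internal and terminal nodes alike, the "ancestral" flavour of
phylogenetic mixed model. Fixed effects carry flat priors and are integrated
analytically; the phylogenetic and residual standard deviations carry
exponential priors. The phylogenetic prior follows the weakly informative
recipe: estimate the residual BM standard deviation from the mean squared
independent contrast of the OLS residuals (computed at terminal nodes, where
contrasts are defined), then set the exponential rate so that 1% of the mass
exceeds three times that estimate; the residual sd gets the analogous prior
from the OLS residual spread. The marginal likelihood uses a single Laplace
approximation at the posterior mode of the two variance parameters — a
lighter stand-in for the nested-Laplace machinery of the original fits.
Bayes factors therefore inherit the approximation, and their verbal scale
(below 3.2 equivalent, 3.2–10 small to substantial, above 10 very strong)
should be read with that in mind. With the phylogenetic sd fixed at zero the
posterior-mode coefficients coincide with OLS exactly, which the tests
assert to 1e-6.

## The synthetic world

The generator's defaults state one world and stay there: 52 species surveyed
at 275 sites, site richness 1–5 with 101/275 single-species sites and mean
2.5 (richness probabilities for 2–5 chosen as 0.65/0.25/0.05/0.05 of the
multi-species mass, the simplest profile with that mean); a constant-rate
birth-death tree (birth 0.2/Myr, death 0.05/Myr — a net rate in the range of
a several-tens-of-Myr radiation to ~150 species); flowering midpoints von
Mises around September with concentration 1.3, which puts the Rayleigh
`rbar` near 0.55 at n = 52; durations uniform on 2–6 months; log pistil
length Brownian around 40 mm (total sd 0.35 on the log scale) with 5%
lognormal measurement noise; colour profiles with heritable per-organ base
colours (Brownian per channel, sd 0.2 across the tree), fixed organ offsets,
perianth-biased Dirichlet signal weights, and 3–6 organs per species.

Trait models: *speciational* adds a `N(0, tau2)` jump at the origin of every
edge plus weak drift, so variance tracks node counts, not path lengths;
*allopatric_bm* is plain Brownian motion; *negative_interactions* multiplies
the instantaneous Brownian rate by `1 + gamma * (L(t) - 1)` with `L(t)` the
number of coexisting lineages — the simplest mechanism whose rates rise with
standing diversity (global lineage count stands in for local diversity; no
explicit geography enters trait evolution). Generators return the realized
per-edge rates so estimator-recovery tests have a ground truth.

Assembly models: *random* draws species by a lognormal commonness profile;
*divergence_filter* adds members with probability proportional to their
minimum trait distance to the current members, producing the overdispersion
FRic is meant to detect; *dispersal_limited* weights draws by an exponential
kernel (default scale 80 km) around species-specific range centres in a
600 km square region.

What a green test does and does not establish: the synthetic world matches
the survey's *shape* (sizes, richness profile, signal concentrations), but
real data differ in ways the generator does not emulate — spatially
autocorrelated richness, phylogenetically clumped range sizes, correlated
organ colours within syndromes, observation error in incidence. Green
calibration and power tests certify the statistical machinery, not any
empirical claim about a particular flora.

## Numerical choices and limitations

* Ultrametricity uses a 1e-6 relative tolerance on root-to-tip depths;
  trees failing it are rejected by `ridge_rates` (rates need a common time
  scale) but tolerated elsewhere.
* The transportation simplex perturbs supplies by 1e-11 and re-solves the
  final basis exactly; hull volumes jitter by 1e-9 relative.
* OU's `alpha` is searched on a log scale from 1e-9 to 50 per unit tree
  height; the boundary BM fit is always compared.
* The swap chain cannot leave matrices with no 2x2 checkerboard (e.g. all
  ones); such inputs are returned unchanged with a message.
* Verdicts use empirical type-7 quantiles; with 199 replicates the test's
  size is ~5% by exchangeability, and discreteness makes it mildly
  conservative.
* The discrimination of the negative-interactions model from gradual drift
  is performed *paired on the same tree* (rate–age slope under each model):
  ridge rates carry a 1/length artefact common to both models which the
  pairing cancels; unpaired slopes are noticeably noisier.
* Species present in communities but absent from the phylogeny are a hard
  error — augmenting the tree with polytomies is upstream curation, not
  re-implemented here. Unsequenced species should be excluded before rate
  analyses, mirroring standard practice.
* No abundance-weighted metrics (surveys are incidence-only), no
  multi-optimum OU or early-burst models, no UV reflectance or pixel-level
  image handling.
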