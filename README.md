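# floradiverge

Tools for asking how flower colour, floral morphology and flowering
phenology are distributed across ecological communities and across a dated
phylogeny — and for discriminating three models of floral trait evolution in
a radiation:

* **speciational** — phenotypic change concentrated at divergence events
  (low phylogenetic signal, trait–diversification rates positively coupled);
* **allopatric divergence** — gradual Brownian drift (signal consistent with
  BM, disparity-through-time inside the BM envelope, no rate coupling);
* **negative interactions** — divergence driven by competition or
  reproductive interference in sympatry (trait overdispersion inside
  communities, trait-evolution rates rising with standing diversity, hence
  negatively coupled to diversification).

The package is aimed at community phylogenetics / floral macroevolution
studies built on four inputs: a dated Newick phylogeny; a site-by-species
incidence survey with site coordinates (km); a per-species table of pistil
length and flowering start/end months; and a per-photo, per-organ flower
colour table (RGB in [0,1] plus each organ's share of the inflorescence
colour signal).

## What it computes

* **Colour profiles and chromatic distances** — per-species organ-weighted
  colour point sets; pairwise earth-mover (transportation) distances with
  Euclidean RGB ground metric, solved exactly; PCA per organ class and
  classical PCoA embeddings (`aggregate_profile`, `emd`,
  `color_distance_matrix`, `pca_first_pc`, `pcoa_embed`).
* **Phenology on the circle** — species flowering angles, the Rayleigh test
  of flowering synchrony (statistic = mean resultant length
  r&#773; = |&Sigma;e^{i&theta;}|/n), wrap-aware phenological overlap, and
  geographic overlap of occurrence ranges (`rayleigh_test`,
  `phenology_overlap`, `geographic_overlap`, `cooccurring_overlap_summary`).
* **Community assembly** — per-site functional richness
  FRic = vol(hull(community)) / vol(hull(pool)) for colour (leading PCoA
  axes) and pistil length (range ratio), mean pairwise phylogenetic distance
  (MPD), and two-sided tail tests of the regional means against the
  independent-swap (fixed-fixed checkerboard) and dispersal
  (exponential-kernel) null models (`assembly_metrics`, `assembly_test`,
  `independent_swap`, `dispersal_null`).
* **Macroevolution** — Blomberg's K (permutation test), Pagel's &lambda;
  (likelihood-ratio test), BM / single-optimum OU / white-noise model
  selection by AICc, disparity-through-time with a 1000-simulation BM
  envelope, and lineage-through-time curves (`blomberg_k`, `pagel_lambda`,
  `fit_trait_models`, `dtt`, `ltt`).
* **Branch rates** — per-edge trait-evolution rates by phylogenetic ridge
  regression (GCV-tuned penalty), the inverse equal-splits (DR)
  diversification proxy (pluggable: externally estimated per-edge rates are
  accepted), and a phylogenetic mixed model of
  log(trait rate + 0.1) on standardized log diversification rate and branch
  age with a weakly informative BM-contrast prior, Laplace-approximated
  marginal likelihoods and Bayes-factor comparison (`ridge_rates`,
  `div_rate_proxy`, `branch_rate_table`, `rate_regression`, `bayes_factor`).
* **Synthetic worlds** — seeded generators for all the above inputs under
  the three trait models and three community-assembly mechanisms
  (`synth_config`, `sim_world`, `sim_tree`, `sim_traits`,
  `sim_communities`, `sim_color_profiles`, `sim_phenology`, `write_world`).

## Worked example

A synthetic survey-scale world (52 species, 275 sites) whose communities are
assembled by a divergence filter on pistil length:

```r
library(floradiverge)

cfg     <- synth_config(seed = 11)          # 52 species, 275 sites
tree    <- sim_tree(cfg)
traits  <- sim_phenology(tree, cfg)
profile <- sim_color_profiles(tree, cfg)
pistil  <- setNames(traits$pistil_length, traits$species)
comm    <- sim_communities(tree, trait = as.matrix(pistil), cfg = cfg,
                           model = "divergence_filter")

rayleigh_test(flowering_angles(traits))
#> rbar = 0.537, p = 1.1e-07, n = 52

D   <- color_distance_matrix(profile)
emb <- pcoa_embed(D, k = 5)
res <- assembly_test(comm, tree = tree, embedding = emb, traits = traits,
                     n_reps = 999, seed = 1)
#> fric_color : observed 0.04799 vs 999 nulls [0.03562, 0.06423] -> within
#> fric_pistil: observed 0.5669  vs 999 nulls [0.4152, 0.5153]  -> above
#> mpd        : observed 34.72   vs 999 nulls [32.12, 35.13]    -> within
```

Flowering is strongly synchronous (r&#773; = 0.537: a unimodal flowering
season), yet communities pack in *more* pistil-length diversity than the
swap null allows — exactly the overdispersion the divergence filter built in
— while colour FRic and MPD stay within their null envelopes, as they should
for a trait the filter ignored.

```r
pc1 <- pca_first_pc(dominant_color(profile))$scores
blomberg_k(tree, pc1, seed = 1)      # K = 0.09, p = 0.050
pagel_lambda(tree, pc1)              # lambda = 0.69, p < 0.001

rr  <- ridge_rates(tree, pc1)
brt <- branch_rate_table(tree, rr$rate, div_rate_proxy(tree))
rate_regression(brt, c("divrate", "age"), tree)
#> Phylogenetic branch-rate regression (divrate + age)
#>         term estimate   lower   upper
#>  (Intercept)  -2.0337 -2.1633 -1.9040
#>      divrate   0.1594  0.0716  0.2472
#>          age   0.0187 -0.0624  0.0997
#> sigma_p = 0.0996, sigma_e = 0.41, logML = -65.395
```

The coefficients are posterior-mode estimates with 95% credible intervals;
`age` is the child node's distance from the root (large = recent), so a
credibly positive `age` slope would indicate rates rising toward the
present, the negative-interactions signature.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the whole pipeline from scratch on a seeded synthetic survey-scale
world — phenology statistics, colour distances and embedding, both
community-assembly null models at 1000 replicates, phylogenetic signal and
model selection, disparity- and lineage-through-time, branch rates and the
rate regressions with their Bayes factors — logging each stage's results and
writing the JSON report to `--out`.

## Vignette

`vignettes/floral-divergence-methods.Rmd` documents the models and their
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, the numerical choices
(exact transportation simplex, hull-volume enumeration, Laplace
approximation), and known limitations.
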