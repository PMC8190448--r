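# Seeded generators reproducing the statistical structure of a regional
# radiation survey: a dated tree, floral traits under three competing
# evolutionary models, organ-weighted colour profiles, flowering phenology
# and site-by-species communities under three assembly models.

#' Synthetic-world configuration
#'
#' Defaults describe a survey-scale world: 52 species over 275 sites with
#' site richness 1-5 (mean 2.5, about 37\% of sites holding a single
#' species), a constant-rate birth-death tree, September-centred flowering
#' with von Mises concentration kappa = 1.3 (which puts the mean resultant
#' length of flowering angles near 0.55 at this sample size), and traits
#' generated under one of three models: `speciational` (a phenotypic jump at
#' every divergence plus weak gradual drift), `allopatric_bm` (pure gradual
#' Brownian drift) and `negative_interactions` (Brownian drift whose rate
#' grows with the number of coexisting lineages, so divergence accelerates
#' toward the present).
#'
#' @param n_species,n_sites World size.
#' @param richness_probs Probabilities of site richness 1..5.
#' @param birth,death Speciation/extinction rates (1/Myr) of the tree
#'   simulator.
#' @param trait_model,assembly_model Generative models (see Details).
#' @param kappa Von Mises concentration of flowering midpoints.
#' @param region_km Side of the square study region.
#' @param seed Integer master seed.
#' @param ... Model-specific parameters overriding the defaults:
#'   `sigma2` (BM rate), `tau2` (speciational jump variance), `sigma2_bm`
#'   (speciational residual drift), `gamma` (diversity-dependence strength),
#'   `rho_km` (dispersal-limited kernel scale).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_species = 52, n_sites = 275,
                         richness_probs = c(101, 174 * c(0.65, 0.25, 0.05, 0.05)) / 275,
                         birth = 0.2, death = 0.05,
                         trait_model = c("allopatric_bm", "speciational",
                                         "negative_interactions"),
                         assembly_model = c("random", "divergence_filter",
                                            "dispersal_limited"),
                         kappa = 1.3, region_km = 600, seed = 1, ...) {
  stopifnot(n_species >= 4, n_sites >= 1, birth > death, death >= 0, kappa >= 0)
  cfg <- list(n_species = n_species, n_sites = n_sites,
              richness_probs = richness_probs / sum(richness_probs),
              birth = birth, death = death,
              trait_model = match.arg(trait_model),
              assembly_model = match.arg(assembly_model),
              kappa = kappa, region_km = region_km, seed = as.integer(seed),
              sigma2 = 1, tau2 = 1, sigma2_bm = 0.01, gamma = 0.1,
              rho_km = 80)
  extra <- list(...)
  cfg[names(extra)] <- extra
  class(cfg) <- "synth_config"
  cfg
}

#' Simulate a dated birth-death tree
#'
#' Constant-rate birth-death tree conditioned on the number of extant tips,
#' ultrametric and fully seeded.
#'
#' @param cfg A [synth_config].
#' @return A validated ultrametric `phylo` with `n_species` tips labelled
#'   `sp01`, `sp02`, ...
#' @export
sim_tree <- function(cfg) {
  set.seed(.child_seed(cfg$seed, 1))
  tr <- NULL
  for (try in 1:20) {
    tr <- tryCatch(ape::rphylo(cfg$n_species, cfg$birth, cfg$death),
                   error = function(e) NULL)
    if (!is.null(tr)) break
  }
  if (is.null(tr)) stop("birth-death simulation failed after 20 retries", call. = FALSE)
  tr$tip.label <- sprintf("sp%02d", seq_len(cfg$n_species))
  validate_phylogeny(tr)
}

# lineage count as a step function of time from the root
.lineage_counter <- function(tree) {
  lt <- ltt(tree)
  function(t) {
    k <- findInterval(t, lt$time)  # nodes at exactly t count as passed
    if (k == 0) 1 else lt$n_lineages[k]
  }
}

#' Simulate tip traits under one of three evolutionary models
#'
#' `allopatric_bm`: Brownian motion with rate `sigma2` — divergence grows
#' with time since separation.  `speciational`: every edge receives a
#' `N(0, tau2)` jump at its origin (the divergence event) plus weak Brownian
#' drift `sigma2_bm` — divergence grows with the number of speciation events,
#' not elapsed time.  `negative_interactions`: Brownian motion whose
#' instantaneous rate is multiplied by `1 + gamma * (L(t) - 1)` with `L(t)`
#' the number of coexisting lineages, so trait change accelerates as standing
#' diversity accumulates toward the present.
#'
#' @param tree Dated `phylo`.
#' @param model One of `"allopatric_bm"`, `"speciational"`,
#'   `"negative_interactions"`.
#' @param params Named list overriding `sigma2`, `tau2`, `sigma2_bm`,
#'   `gamma`.
#' @param seed Optional integer seed.
#' @return List with `tips` (named vector), `edge_rates` (realized variance
#'   per unit time for every edge, `tree$edge` order) and `model`.
#' @export
sim_traits <- function(tree, model = c("allopatric_bm", "speciational",
                                       "negative_interactions"),
                       params = list(), seed = NULL) {
  model <- match.arg(model)
  p <- utils::modifyList(list(sigma2 = 1, tau2 = 1, sigma2_bm = 0.01,
                              gamma = 0.1), params)
  if (!is.null(seed)) set.seed(seed)
  depths <- .node_depths(tree)
  ne <- nrow(tree$edge)
  len <- tree$edge.length
  edge_var <- switch(model,
    allopatric_bm = p$sigma2 * len,
    speciational = p$tau2 + p$sigma2_bm * len,
    negative_interactions = {
      Lf <- .lineage_counter(tree)
      lt <- ltt(tree)
      brk <- c(lt$time, .tree_height(tree))
      vapply(seq_len(ne), function(e) {
        t0 <- depths[tree$edge[e, 1]]; t1 <- depths[tree$edge[e, 2]]
        cuts <- unique(c(t0, brk[brk > t0 & brk < t1], t1))
        segs <- diff(cuts)
        mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
        sum(p$sigma2 * (1 + p$gamma * (vapply(mids, Lf, numeric(1)) - 1)) * segs)
      }, numeric(1))
    })
  changes <- stats::rnorm(ne, 0, sqrt(pmax(edge_var, 0)))
  # accumulate along root-to-node paths (preorder)
  nnode <- ape::Ntip(tree) + tree$Nnode
  val <- numeric(nnode)
  pr <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(paste(pr$edge[, 1], pr$edge[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
  for (e in ord) {
    val[tree$edge[e, 2]] <- val[tree$edge[e, 1]] + changes[e]
  }
  tips <- val[seq_len(ape::Ntip(tree))]
  names(tips) <- tree$tip.label
  list(tips = tips,
       edge_rates = ifelse(len > 0, edge_var / len, NA_real_),
       model = model)
}

# Best-Fisher von Mises sampler (concentration kappa, mean direction mu)
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1]); f <- (1 + r * z) / (r + z); cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Simulate flowering phenology and pistil length
#'
#' Flowering midpoints are von Mises around September (the regional flowering
#' peak) with concentration `kappa`; durations are uniform on 2-6 months and
#' periods may wrap the year end.  Log pistil length follows Brownian motion
#' on the tree around a 40 mm root state (total sd about 0.35 on the log
#' scale) plus small lognormal measurement noise.
#'
#' @param tree Dated `phylo`.
#' @param cfg A [synth_config].
#' @return A [trait_table].
#' @export
sim_phenology <- function(tree, cfg) {
  set.seed(.child_seed(cfg$seed, 2))
  n <- ape::Ntip(tree)
  ang <- .rvonmises(n, 2 * pi * (9 - 1) / 12, cfg$kappa)
  mid <- (round(ang * 12 / (2 * pi)) %% 12) + 1
  dur <- sample(2:6, n, replace = TRUE)
  start <- ((mid - 1 - floor((dur - 1) / 2)) %% 12) + 1
  end <- ((start - 1 + dur - 1) %% 12) + 1
  Tht <- .tree_height(tree)
  sig <- sim_traits(tree, "allopatric_bm",
                    params = list(sigma2 = 0.35^2 / Tht))$tips
  pistil <- exp(log(40) + sig + stats::rnorm(n, 0, 0.05))
  trait_table(tree$tip.label, pistil, start, end)
}

#' Simulate organ-weighted colour profiles
#'
#' Each organ class has a heritable base colour (Brownian motion on the tree
#' per RGB channel around mid-grey) plus a fixed organ offset and small
#' per-species noise, clipped to the unit cube.  Every species shows the
#' perianth and pistil plus a random subset of further organs (3-6 in total),
#' with Dirichlet signal weights biased toward the perianth.
#'
#' @param tree Dated `phylo`.
#' @param cfg A [synth_config].
#' @return A [color_profile].
#' @export
sim_color_profiles <- function(tree, cfg) {
  set.seed(.child_seed(cfg$seed, 3))
  organs <- c("perianth", "pistil", "pollen_presenter", "nectary", "pedicel",
              "bract")
  alpha <- c(4, 2, 1, 1, 1, 1)
  Tht <- .tree_height(tree)
  n <- ape::Ntip(tree)
  base <- lapply(organs, function(o) {
    sapply(1:3, function(ch)
      0.5 + sim_traits(tree, "allopatric_bm",
                       params = list(sigma2 = 0.04 / Tht))$tips)
  })
  offset <- matrix(stats::rnorm(length(organs) * 3, 0, 0.15), ncol = 3)
  rows <- list()
  for (i in seq_len(n)) {
    k <- sample(3:6, 1)
    org_idx <- c(1:2, sample(3:6, k - 2))
    w <- stats::rgamma(k, alpha[org_idx], 1)
    w <- w / sum(w)
    cols <- t(vapply(seq_along(org_idx), function(j) {
      oi <- org_idx[j]
      pmin(1, pmax(0, base[[oi]][i, ] + offset[oi, ] + stats::rnorm(3, 0, 0.05)))
    }, numeric(3)))
    rows[[i]] <- data.frame(species = tree$tip.label[i],
                            organ = organs[org_idx],
                            R = cols[, 1], G = cols[, 2], B = cols[, 3],
                            weight = w)
  }
  color_profile(do.call(rbind, rows))
}

#' Simulate community assembly
#'
#' Assigns species to sites at the configured richness profile under one of
#' three mechanisms: `random` (frequency-weighted draws from a lognormal
#' commonness profile), `divergence_filter` (members added sequentially with
#' probability proportional to their minimum trait distance to the current
#' members — produces trait overdispersion that FRic should detect) and
#' `dispersal_limited` (draws weighted by an exponential kernel around a
#' species-specific range centre).
#'
#' @param tree Dated `phylo` (supplies the species labels).
#' @param trait Per-species trait values (vector or matrix, rownames/names =
#'   species) used by the divergence filter.
#' @param cfg A [synth_config].
#' @param model Override `cfg$assembly_model`.
#' @return A [community_data]; species that were never drawn are dropped.
#' @export
sim_communities <- function(tree, trait = NULL, cfg,
                            model = cfg$assembly_model) {
  set.seed(.child_seed(cfg$seed, 4))
  spp <- tree$tip.label
  n <- length(spp)
  ns <- cfg$n_sites
  xy <- matrix(stats::runif(2 * ns, 0, cfg$region_km), ncol = 2,
               dimnames = list(sprintf("site%03d", seq_len(ns)), c("x", "y")))
  rich <- sample(seq_along(cfg$richness_probs), ns, replace = TRUE,
                 prob = cfg$richness_probs)
  rich <- pmin(rich, n)
  commonness <- stats::rlnorm(n, 0, 1)
  M <- matrix(0, ns, n, dimnames = list(rownames(xy), spp))
  if (model == "divergence_filter") {
    if (is.null(trait)) stop("divergence_filter needs trait values", call. = FALSE)
    Tm <- as.matrix(trait)
    Tm <- Tm[spp, , drop = FALSE]
    TD <- as.matrix(stats::dist(Tm))
  }
  if (model == "dispersal_limited") {
    centers <- matrix(stats::runif(2 * n, 0, cfg$region_km), ncol = 2)
    K <- exp(-as.matrix(stats::dist(rbind(xy, centers)))[seq_len(ns),
             ns + seq_len(n)] / cfg$rho_km)
  }
  for (s in seq_len(ns)) {
    k <- rich[s]
    picked <- switch(model,
      random = sample.int(n, k, prob = commonness),
      dispersal_limited = sample.int(n, k, prob = K[s, ] * commonness),
      divergence_filter = {
        members <- sample.int(n, 1, prob = commonness)
        while (length(members) < k) {
          cand <- setdiff(seq_len(n), members)
          w <- matrixStats::colMins(TD[members, cand, drop = FALSE])
          if (all(w <= 0)) w <- w + 1
          members <- c(members, cand[sample.int(length(cand), 1, prob = w)])
        }
        members
      })
    M[s, picked] <- 1
  }
  keep <- colSums(M) > 0
  community_data(M[, keep, drop = FALSE], xy)
}

#' Simulate a complete synthetic world
#'
#' Tree, colour profiles, phenology and pistil traits, and communities
#' (assembled, under the divergence filter, on the dominant flower colour).
#'
#' @param cfg A [synth_config].
#' @return List with `tree`, `profile`, `traits`, `community`, `cfg`.
#' @export
sim_world <- function(cfg = synth_config()) {
  tree <- sim_tree(cfg)
  profile <- sim_color_profiles(tree, cfg)
  traits <- sim_phenology(tree, cfg)
  comm <- sim_communities(tree, trait = dominant_color(profile), cfg = cfg)
  list(tree = tree, profile = profile, traits = traits, community = comm,
       cfg = cfg)
}

#' Write a synthetic world to disk
#'
#' Newick tree plus four CSVs (incidence, coordinates, traits, colour rows)
#' in the formats the readers consume.
#'
#' @param world A [sim_world()] result.
#' @param dir Output directory (created if needed).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phylogeny(world$tree, file.path(dir, "tree.nwk"))
  write_community(world$community, file.path(dir, "incidence.csv"),
                  file.path(dir, "coordinates.csv"))
  write_traits(world$traits, file.path(dir, "traits.csv"))
  pf <- as.data.frame(world$profile)
  pf$photo_id <- "synthetic"
  pf$proportion <- pf$weight
  utils::write.csv(pf[, c("species", "photo_id", "organ", "R", "G", "B",
                          "proportion")],
                   file.path(dir, "color_rows.csv"), row.names = FALSE)
  invisible(dir)
}
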