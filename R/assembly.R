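#' Convex-hull volume of a point cloud
#'
#' Exact hull volume used by functional richness.  In one dimension this is
#' the range; in two, the shoelace area of the planar hull; in higher
#' dimensions the hull facets are enumerated by brute force (every supporting
#' hyperplane through d points) and the volume accumulated as pyramids to the
#' centroid.  Point sets whose affine span has lower dimension than the
#' embedding space have zero volume.  A deterministic relative jitter of 1e-9
#' breaks ties among coplanar points (simulation-of-simplicity); the induced
#' volume error is of the same order.
#'
#' @param points Numeric matrix, one point per row.
#' @return Nonnegative hull volume.
#' @export
hull_volume <- function(points) {
  P <- as.matrix(points)
  storage.mode(P) <- "double"
  d <- ncol(P); n <- nrow(P)
  if (d == 1L) return(if (n) max(P) - min(P) else 0)
  if (n < d + 1L) return(0)
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc, nu = 0, nv = 0)$d
  scale <- max(sv, 0)
  if (scale == 0 || sum(sv > 1e-9 * scale) < d) return(0)  # affinely degenerate
  if (d == 2L) {
    h <- grDevices::chull(P)
    x <- P[h, 1]; y <- P[h, 2]
    return(abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2)
  }
  if (n == d + 1L) {
    V <- P[-1, , drop = FALSE] - matrix(P[1, ], d, d, byrow = TRUE)
    return(abs(.det_small(V)) / factorial(d))
  }
  .hull_volume_facets(P, ctr, scale)
}

# deterministic pseudo-random jitter (no RNG state touched)
.sos_jitter <- function(n, d, scale) {
  z <- sin((seq_len(n * d)) * 127.1 + 311.7) * 43758.5453
  matrix((z - floor(z)) - 0.5, n, d) * (2e-9 * scale)
}

.hull_volume_facets <- function(P, ctr, scale) {
  n <- nrow(P); d <- ncol(P)
  P <- P + .sos_jitter(n, d, scale)
  combs <- utils::combn(n, d)
  nc <- ncol(combs)
  vol <- 0
  chunk <- max(1L, as.integer(2e6 / n))
  for (s0 in seq(1L, nc, by = chunk)) {
    idx <- s0:min(s0 + chunk - 1L, nc)
    cb <- combs[, idx, drop = FALSE]
    base <- P[cb[1, ], , drop = FALSE]
    U <- lapply(seq_len(d - 1), function(r) P[cb[r + 1, ], , drop = FALSE] - base)
    N <- .generalized_cross(U, d)                     # |idx| x d normals
    nrm <- sqrt(rowSums(N^2))
    ok <- nrm > 1e-12 * scale^(d - 1)
    if (!any(ok)) next
    N <- N[ok, , drop = FALSE]; base_ok <- base[ok, , drop = FALSE]
    offs <- rowSums(N * base_ok)
    S <- N %*% t(P) - offs                            # sides of every point
    tolside <- 1e-10 * scale^(d - 1) * scale
    supp <- (matrixStats::rowMaxs(S) <= tolside) | (matrixStats::rowMins(S) >= -tolside)
    if (!any(supp)) next
    w <- matrix(ctr, sum(supp), d, byrow = TRUE) - base_ok[supp, , drop = FALSE]
    vol <- vol + sum(abs(rowSums(N[supp, , drop = FALSE] * w))) / factorial(d)
  }
  vol
}

# Generalized cross product of d-1 stacked row-vector matrices in R^d:
# returns N with rows n such that det(rbind(u_1,...,u_{d-1}, w)) = n . w.
.generalized_cross <- function(U, d) {
  if (d == 3L) {
    u <- U[[1]]; v <- U[[2]]
    return(cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                 u[, 1] * v[, 2] - u[, 2] * v[, 1]))
  }
  m <- nrow(U[[1]])
  N <- matrix(0, m, d)
  det3v <- function(a, b, c, i, j, k) {
    a[, i] * (b[, j] * c[, k] - b[, k] * c[, j]) -
    a[, j] * (b[, i] * c[, k] - b[, k] * c[, i]) +
    a[, k] * (b[, i] * c[, j] - b[, j] * c[, i])
  }
  if (d == 4L) {
    a <- U[[1]]; b <- U[[2]]; cc <- U[[3]]
    cols <- 1:4
    for (k in cols) {
      rest <- cols[-k]
      N[, k] <- (-1)^k * det3v(a, b, cc, rest[1], rest[2], rest[3])
    }
    return(N)
  }
  # generic (slow) fallback for d >= 5: cofactor expansion via dense det
  for (r in seq_len(m)) {
    M <- do.call(rbind, lapply(U, function(u) u[r, ]))
    for (k in seq_len(d)) {
      N[r, k] <- (-1)^(d + k) * det(M[, -k, drop = FALSE])
    }
  }
  N
}

#' Functional richness (FRic)
#'
#' Ratio of the convex-hull volume of a community's species in trait space to
#' the hull volume of the whole species pool: the fraction of the regional
#' trait space a community occupies.  In one dimension the volume is the
#' range.  Communities whose points are affinely degenerate in the pool's
#' space score 0.
#'
#' @param community_points,pool_points Matrices (points x trait dimensions);
#'   the community must use the same columns as the pool.
#' @return Proportion in `[0,1]` (up to hull-volume rounding).
#' @export
fric <- function(community_points, pool_points) {
  community_points <- as.matrix(community_points)
  pool_points <- as.matrix(pool_points)
  if (nrow(community_points) <= 2)
    stop("FRic needs more than two species in the community", call. = FALSE)
  pv <- hull_volume(pool_points)
  if (pv <= 0) stop("species pool has zero trait-space volume", call. = FALSE)
  min(1, hull_volume(community_points) / pv)
}

#' Trait-space coordinates for one community
#'
#' For `source = "color"` returns the rows of the pool's PCoA embedding for
#' the site's species, restricted to the leading `min(k, richness - 1)` axes
#' (standard FRic practice for small communities); for `source = "pistil"`,
#' the raw pistil lengths as a one-column matrix.
#'
#' @param species Character vector of the site's species.
#' @param source `"color"` or `"pistil"`.
#' @param embedding A [pcoa_embed] result (colour source).
#' @param traits A [trait_table] (pistil source).
#' @param k Maximum number of colour axes (default 5).
#' @return Numeric matrix, one row per species.
#' @export
community_trait_points <- function(species, source = c("color", "pistil"),
                                   embedding = NULL, traits = NULL, k = 5) {
  source <- match.arg(source)
  if (source == "pistil") {
    miss <- setdiff(species, traits$species)
    if (length(miss)) stop("species missing from traits: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    return(matrix(traits[species, "pistil_length"], ncol = 1,
                  dimnames = list(species, "pistil_length")))
  }
  miss <- setdiff(species, rownames(embedding$coords))
  if (length(miss)) stop("species missing from embedding: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d <- min(k, ncol(embedding$coords), length(species) - 1L)
  embedding$coords[species, seq_len(max(1L, d)), drop = FALSE]
}

#' Mean pairwise phylogenetic distance of a community
#'
#' Mean patristic distance over all unordered pairs of the site's species.
#'
#' @param species Character vector (>= 2 species).
#' @param tree A `phylo` object containing them, or a precomputed patristic
#'   distance matrix.
#' @return Mean pairwise distance (tree time units).
#' @export
mpd <- function(species, tree) {
  if (length(species) < 2) stop("MPD needs at least two species", call. = FALSE)
  D <- if (inherits(tree, "phylo")) patristic_distances(tree) else as.matrix(tree)
  D <- D[species, species]
  mean(D[upper.tri(D)])
}

#' Independent-swap randomization of an incidence matrix
#'
#' Fixed-fixed null model: repeated 2x2 checkerboard submatrix swaps preserve
#' every site's richness and every species' occurrence frequency exactly
#' (Gotelli's independent swap).  Matrices with no checkerboard (e.g. all
#' ones) are returned unchanged with a message.
#'
#' @param incidence Binary sites x species matrix.
#' @param iterations Number of swap steps (default 1000 x number of
#'   occurrences).
#' @param seed Optional integer seed.
#' @return A randomized matrix with identical row and column sums.
#' @export
independent_swap <- function(incidence, iterations = NULL, seed = NULL) {
  m <- as.matrix(incidence)
  if (!all(m %in% c(0, 1))) stop("incidence must be binary", call. = FALSE)
  if (is.null(iterations)) iterations <- 1000 * sum(m)
  out <- tryCatch(
    stats::simulate(vegan::nullmodel(m, "swap"), nsim = 1,
                    thin = iterations, burnin = 0, seed = seed)[, , 1],
    error = function(e) {
      if (grepl("checkerboard", conditionMessage(e))) {
        message("no checkerboard submatrix; matrix returned unchanged")
        m
      } else stop(e)
    })
  dimnames(out) <- dimnames(m)
  out
}

# Swap-chain replicate array (sites x species x nsim); burnin/thin in swap
# steps.  Falls back to copies of the input when no checkerboard exists.
.iswap_replicates <- function(m, nsim, thin, burnin, seed = NULL) {
  tryCatch(
    stats::simulate(vegan::nullmodel(m, "swap"), nsim = nsim,
                    thin = thin, burnin = burnin, seed = seed),
    error = function(e) {
      if (grepl("checkerboard", conditionMessage(e))) {
        message("no checkerboard submatrix; null replicates equal the data")
        array(m, dim = c(nrow(m), ncol(m), nsim))
      } else stop(e)
    })
}

#' Dispersal null model
#'
#' Site-richness-preserving randomization accounting for dispersal
#' limitation: each site draws its observed number of species without
#' replacement, with species probabilities proportional to
#' `sum over other sites t where the species occurs of exp(-decay * d(s, t))`.
#' Sites where every species has zero weight fall back to
#' occurrence-frequency-proportional draws.
#'
#' @param community A [community_data] object.
#' @param decay Exponential decay rate (1/km); default 1 / mean pairwise
#'   inter-site distance.
#' @param seed Optional integer seed.
#' @return A randomized incidence matrix with the observed site richnesses.
#' @export
dispersal_null <- function(community, decay = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- .dispersal_weights(community, decay)
  .dispersal_draw(community$incidence, W)
}

.dispersal_weights <- function(community, decay = NULL) {
  D <- site_distances(community)
  if (is.null(decay)) decay <- 1 / mean(D[upper.tri(D)])
  if (decay <= 0) stop("decay rate must be positive", call. = FALSE)
  E <- exp(-decay * D)
  diag(E) <- 0
  E %*% community$incidence
}

.dispersal_draw <- function(m, W) {
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  rich <- rowSums(m)
  freq <- colSums(m)
  nspp <- ncol(m)
  for (s in seq_len(nrow(m))) {
    w <- W[s, ]
    k <- rich[s]
    if (all(w <= 0)) w <- freq
    if (sum(w > 0) < k) w <- w + freq * 1e-9  # ensure enough support
    pick <- sample.int(nspp, k, replace = FALSE, prob = w)
    out[s, pick] <- 1
  }
  out
}

#' Observed metric against a null distribution
#'
#' @param observed Observed scalar metric.
#' @param replicates Vector of null replicate values.
#' @return Object of class `null_distribution`: observed value, replicates,
#'   2.5\%/97.5\% empirical quantiles and a two-sided tail `verdict` in
#'   `below` / `within` / `above`.
#' @export
null_distribution <- function(observed, replicates) {
  q <- stats::quantile(replicates, c(0.025, 0.975), names = FALSE)
  verdict <- if (observed < q[1]) "below" else if (observed > q[2]) "above" else "within"
  structure(list(observed = observed, replicates = replicates,
                 lower_q = q[1], upper_q = q[2], verdict = verdict,
                 n_null = length(replicates)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("observed %.4g vs %d nulls [%.4g, %.4g] -> %s\n",
              x$observed, x$n_null, x$lower_q, x$upper_q, x$verdict))
  invisible(x)
}

# ---- internal machinery for fast metric evaluation --------------------------

.assembly_precomp <- function(community, tree = NULL, embedding = NULL,
                              traits = NULL, k = 5) {
  M <- community$incidence
  spp <- colnames(M)
  pre <- list(spp = spp, k = k)
  rich <- rowSums(M)
  if (!is.null(tree)) {
    miss <- setdiff(spp, tree$tip.label)
    if (length(miss)) stop("community species absent from tree: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    tr <- if (length(setdiff(tree$tip.label, spp))) prune_to_samples(tree, spp) else tree
    pre$Dphy <- patristic_distances(tr)[spp, spp]
  }
  if (!is.null(embedding)) {
    E <- embedding$coords[spp, , drop = FALSE]
    kk <- min(k, ncol(E))
    pre$E <- E
    ds <- unique(pmin(kk, rich[rich > 2] - 1))
    pre$pool_vol <- stats::setNames(
      vapply(ds, function(d) hull_volume(E[, seq_len(d), drop = FALSE]), numeric(1)),
      as.character(ds))
    if (length(ds) && any(pre$pool_vol <= 0))
      stop("species pool has zero colour trait-space volume", call. = FALSE)
  }
  if (!is.null(traits)) {
    miss <- setdiff(spp, traits$species)
    if (length(miss)) stop("traits missing for: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    pre$pistil <- stats::setNames(traits[spp, "pistil_length"], spp)
    pre$pool_range <- diff(range(pre$pistil))
    if (pre$pool_range <= 0)
      stop("species pool has zero pistil-length range", call. = FALSE)
  }
  pre
}

# Per-site metrics for one incidence matrix; returns list of per-site vectors
# (NA where ineligible) for the requested metrics.
.site_metrics <- function(M, pre, metrics) {
  rich <- rowSums(M)
  out <- list()
  if ("mpd" %in% metrics) {
    v <- rowSums((M %*% pre$Dphy) * M)
    mpdv <- ifelse(rich >= 2, v / (rich * (rich - 1)), NA_real_)
    out$mpd <- mpdv
  }
  wantc <- "fric_color" %in% metrics
  wantp <- "fric_pistil" %in% metrics
  if (wantc || wantp) {
    fc <- fp <- rep(NA_real_, nrow(M))
    kk <- if (wantc) min(pre$k, ncol(pre$E)) else NULL
    for (s in which(rich > 2)) {
      idx <- which(M[s, ] == 1)
      r <- length(idx)
      if (wantp) {
        pv <- pre$pistil[idx]
        fp[s] <- (max(pv) - min(pv)) / pre$pool_range
      }
      if (wantc) {
        d <- min(kk, r - 1L)
        pts <- pre$E[idx, seq_len(d), drop = FALSE]
        vol <- if (r == d + 1L) {
          V <- pts[-1, , drop = FALSE] - matrix(pts[1, ], d, d, byrow = TRUE)
          abs(.det_small(V)) / factorial(d)
        } else hull_volume(pts)
        fc[s] <- min(1, vol / pre$pool_vol[[as.character(d)]])
      }
    }
    if (wantc) out$fric_color <- fc
    if (wantp) out$fric_pistil <- fp
  }
  out
}

.metric_means <- function(M, pre, metrics) {
  vapply(.site_metrics(M, pre, metrics),
         function(v) mean(v, na.rm = TRUE), numeric(1))[metrics]
}

#' Per-site assembly metrics
#'
#' Computes, for every site, colour FRic (hull volume of the site's species
#' in the leading PCoA axes over the pool hull volume), pistil FRic (range
#' ratio) and MPD, plus the regional means over eligible sites (richness > 2
#' for FRic, >= 2 for MPD).
#'
#' @param community A [community_data] object.
#' @param tree Dated `phylo` containing the community species (for MPD).
#' @param embedding [pcoa_embed] of the colour distance matrix (for colour
#'   FRic).
#' @param traits [trait_table] (for pistil FRic).
#' @param metrics Character subset of `"fric_color"`, `"fric_pistil"`,
#'   `"mpd"`.
#' @param k Maximum number of colour axes (default 5).
#' @return List with `per_site` (data frame) and `regional_mean` (named
#'   vector).
#' @export
assembly_metrics <- function(community, tree = NULL, embedding = NULL,
                             traits = NULL,
                             metrics = c("fric_color", "fric_pistil", "mpd"),
                             k = 5) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  pre <- .assembly_precomp(community,
                           tree = if ("mpd" %in% metrics) tree,
                           embedding = if ("fric_color" %in% metrics) embedding,
                           traits = if ("fric_pistil" %in% metrics) traits,
                           k = k)
  per_site <- .site_metrics(community$incidence, pre, metrics)
  list(per_site = data.frame(site = rownames(community$incidence), per_site),
       regional_mean = vapply(per_site, function(v) mean(v, na.rm = TRUE),
                              numeric(1))[metrics])
}

#' Null-model tail test of regional assembly metrics
#'
#' Compares observed regional mean FRic / MPD against their distribution over
#' randomized assemblages, generated either by the independent-swap algorithm
#' (site richness and species frequency exactly preserved) or the dispersal
#' null model (richness preserved; species drawn with exponentially
#' distance-decaying probability).  Verdicts use the empirical 2.5\%/97.5\%
#' quantiles of the null means.
#'
#' @inheritParams assembly_metrics
#' @param null `"iswap"` or `"dispersal"`.
#' @param n_reps Number of null assemblages (default 1000).
#' @param decay Dispersal kernel decay rate (1/km); default 1 / mean pairwise
#'   inter-site distance.
#' @param swap_burnin,swap_thin Swap steps before the first replicate and
#'   between replicates; defaults 1000 x and 1 x the number of occurrences.
#' @param seed Optional integer seed.
#' @return List of [null_distribution] objects, one per requested metric.
#' @export
assembly_test <- function(community, tree = NULL, embedding = NULL,
                          traits = NULL,
                          metrics = c("fric_color", "fric_pistil", "mpd"),
                          null = c("iswap", "dispersal"),
                          n_reps = 1000, decay = NULL,
                          swap_burnin = NULL, swap_thin = NULL,
                          seed = NULL, k = 5) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  null <- match.arg(null)
  M <- community$incidence
  pre <- .assembly_precomp(community,
                           tree = if ("mpd" %in% metrics) tree,
                           embedding = if ("fric_color" %in% metrics) embedding,
                           traits = if ("fric_pistil" %in% metrics) traits,
                           k = k)
  rich <- rowSums(M)
  if (all(rich < 2) || (all(rich <= 2) && any(c("fric_color", "fric_pistil") %in% metrics)))
    stop("no eligible sites for the requested metrics", call. = FALSE)
  obs <- .metric_means(M, pre, metrics)
  nulls <- matrix(NA_real_, n_reps, length(metrics),
                  dimnames = list(NULL, metrics))
  if (null == "iswap") {
    occ <- sum(M)
    if (is.null(swap_burnin)) swap_burnin <- 1000 * occ
    if (is.null(swap_thin)) swap_thin <- occ
    reps <- .iswap_replicates(M, n_reps, thin = swap_thin,
                              burnin = swap_burnin, seed = seed)
    for (r in seq_len(n_reps)) {
      nulls[r, ] <- .metric_means(reps[, , r], pre, metrics)
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    W <- .dispersal_weights(community, decay)
    for (r in seq_len(n_reps)) {
      nulls[r, ] <- .metric_means(.dispersal_draw(M, W), pre, metrics)
    }
  }
  res <- lapply(metrics, function(mt) null_distribution(obs[[mt]], nulls[, mt]))
  names(res) <- metrics
  res
}
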