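#' Circular representation of flowering periods
#'
#' Calendar months are mapped onto the circle with month m at angle
#' 2*pi*(m - 1)/12, so January is 0 and the year wraps.  A species'
#' contribution to the circular sample is the circular mean of the angles of
#' all its months in flower, which keeps wrap-around periods (e.g. Nov-Feb)
#' honest.
#'
#' @param start,end Integer months in 1..12 (the period may wrap).
#' @return `months_to_angle()`: a single angle in `[0, 2*pi)`.
#' @export
months_to_angle <- function(start, end) {
  months <- .months_in_flower(start, end)
  th <- 2 * pi * (months - 1) / 12
  ang <- atan2(mean(sin(th)), mean(cos(th)))
  if (ang < 0) ang <- ang + 2 * pi
  # a diametrically balanced period has no defined mean direction
  if (sqrt(mean(sin(th))^2 + mean(cos(th))^2) < 1e-12) ang <- 0
  ang
}

#' @rdname months_to_angle
#' @param traits A [trait_table].
#' @return `flowering_angles()`: named vector of angles, one per species.
#' @export
flowering_angles <- function(traits) {
  vapply(seq_len(nrow(traits)),
         function(i) months_to_angle(traits$flower_start[i], traits$flower_end[i]),
         numeric(1)) |> stats::setNames(traits$species)
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether angles (one per species, the circular mean of its months in
#' flower) are uniformly distributed around the year or concentrated.  The
#' statistic reported is the mean resultant length rbar in `[0,1]`; the
#' p-value uses the standard large-sample approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with `R = n * rbar`.
#'
#' @param angles Numeric vector of angles in radians (n >= 2).
#' @return List with `statistic` (rbar), `p.value` and `n`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 2) stop("Rayleigh test needs n >= 2 angles", call. = FALSE)
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  R <- n * rbar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(statistic = rbar, p.value = min(1, p), n = n)
}

#' Phenological overlap between two flowering periods
#'
#' Proportion of the months of the shorter-flowering species that fall inside
#' the flowering period of the longer-flowering species (wrap-aware):
#' `|A intersect B| / min(|A|, |B|)`.
#'
#' @param a,b Length-2 integer vectors `c(start, end)` in months.
#' @return Proportion in `[0,1]`.
#' @export
phenology_overlap <- function(a, b) {
  ma <- .months_in_flower(a[1], a[2])
  mb <- .months_in_flower(b[1], b[2])
  length(intersect(ma, mb)) / min(length(ma), length(mb))
}

#' @rdname phenology_overlap
#' @param traits A [trait_table].
#' @return `phenology_overlap_matrix()`: symmetric species x species matrix
#'   with unit diagonal.
#' @export
phenology_overlap_matrix <- function(traits) {
  n <- nrow(traits)
  periods <- lapply(seq_len(n), function(i)
    c(traits$flower_start[i], traits$flower_end[i]))
  M <- diag(1, n)
  dimnames(M) <- list(traits$species, traits$species)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      M[i, j] <- M[j, i] <- phenology_overlap(periods[[i]], periods[[j]])
    }
  }
  attr(M, "kind") <- "phenology"
  M
}

#' Geographic overlap between two species' occurrences
#'
#' Range size is approximated by occurrence-site count.  The overlap is the
#' fraction of the smaller-ranged species' sites lying within `radius_km` of
#' any occurrence of the larger-ranged species (ties in range size broken by
#' label order, first label treated as the smaller range).
#'
#' @param occ_a,occ_b Two-column matrices of site coordinates (km).
#' @param radius_km Distance within which two occurrences count as shared
#'   range (default 20 km).
#' @return Proportion in `[0,1]`.
#' @export
geographic_overlap <- function(occ_a, occ_b, radius_km = 20) {
  occ_a <- as.matrix(occ_a); occ_b <- as.matrix(occ_b)
  if (!nrow(occ_a) || !nrow(occ_b))
    stop("both species must occur somewhere", call. = FALSE)
  if (nrow(occ_a) <= nrow(occ_b)) { small <- occ_a; big <- occ_b }
  else { small <- occ_b; big <- occ_a }
  d2 <- outer(rowSums(small^2), rowSums(big^2), "+") - 2 * tcrossprod(small, big)
  d2[d2 < 0] <- 0
  mean(matrixStats::rowMins(d2) <= radius_km^2)
}

#' @rdname geographic_overlap
#' @param community A [community_data] object.
#' @return `geographic_overlap_matrix()`: symmetric species x species matrix
#'   with unit diagonal.
#' @export
geographic_overlap_matrix <- function(community, radius_km = 20) {
  M <- community$incidence
  spp <- colnames(M)
  occ <- lapply(spp, function(s) community$xy[M[, s] == 1, , drop = FALSE])
  n <- length(spp)
  G <- diag(1, n); dimnames(G) <- list(spp, spp)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      # ties in range size resolve by label order: occ_a enters first
      G[i, j] <- G[j, i] <- geographic_overlap(occ[[i]], occ[[j]], radius_km)
    }
  }
  attr(G, "kind") <- "geography"
  G
}

#' Flowering overlap of co-occurring species pairs
#'
#' Counts, across all sites, how many unique unordered species pairs co-occur
#' in at least one site, how many of those pairs overlap in flowering time
#' (phenological overlap > 0), and how many multi-species sites contain at
#' least one overlapping pair.
#'
#' @param community A [community_data] object.
#' @param traits A [trait_table] covering every community species.
#' @return List with `pairs_overlapping`, `pairs_total`, `sites_with_overlap`,
#'   `multispecies_sites`.
#' @export
cooccurring_overlap_summary <- function(community, traits) {
  M <- community$incidence
  spp <- colnames(M)
  missing <- setdiff(spp, traits$species)
  if (length(missing))
    stop("traits missing for: ", paste(missing, collapse = ", "), call. = FALSE)
  P <- phenology_overlap_matrix(traits)[spp, spp]
  co <- crossprod(M) > 0            # species pairs sharing >= 1 site
  diag(co) <- FALSE
  iu <- upper.tri(co) & co
  pairs_total <- sum(iu)
  pairs_overlapping <- sum(iu & P > 0)
  rich <- rowSums(M)
  multi <- which(rich >= 2)
  site_ok <- vapply(multi, function(s) {
    idx <- which(M[s, ] == 1)
    any(P[idx, idx][upper.tri(diag(length(idx)))] > 0)
  }, logical(1))
  list(pairs_overlapping = pairs_overlapping,
       pairs_total = pairs_total,
       sites_with_overlap = sum(site_ok),
       multispecies_sites = length(multi))
}
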