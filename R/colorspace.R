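#' Species colour profiles
#'
#' A colour profile represents each species' inflorescence as a weighted set
#' of colour points: one RGB centroid per floral organ (pistil, perianth,
#' pollen presenter, ...) together with the proportion of the inflorescence
#' colour signal that organ contributes.  Weights sum to 1 within each
#' species; colours live in the RGB unit cube.
#'
#' @param df Data frame with columns `species`, `organ`, `R`, `G`, `B`,
#'   `weight`.
#' @return The validated data frame with class `color_profile` prepended.
#' @export
color_profile <- function(df) {
  need <- c("species", "organ", "R", "G", "B", "weight")
  if (!all(need %in% names(df)))
    stop("colour profile needs columns ", paste(need, collapse = ", "), call. = FALSE)
  rgb <- as.matrix(df[, c("R", "G", "B")])
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 1))
    stop("colours must lie in the RGB unit cube", call. = FALSE)
  if (any(df$weight <= 0)) stop("organ weights must be positive", call. = FALSE)
  sums <- tapply(df$weight, df$species, sum)
  bad <- abs(sums - 1) > 1e-9
  if (any(bad))
    stop("organ weights must sum to 1 per species; off for: ",
         paste(names(sums)[bad], collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[, need]
  class(df) <- c("color_profile", "data.frame")
  df
}

#' @rdname color_profile
#' @param profile A `color_profile`.
#' @param species A species name present in the profile.
#' @return `profile_entry()`: a list with `points` (organs x 3 RGB matrix) and
#'   `weights` (summing to 1).
#' @export
profile_entry <- function(profile, species) {
  rows <- profile[profile$species == species, , drop = FALSE]
  if (!nrow(rows)) stop("species not in profile: ", species, call. = FALSE)
  list(points = as.matrix(rows[, c("R", "G", "B")]),
       weights = rows$weight / sum(rows$weight),
       organs = rows$organ)
}

#' Aggregate per-photo organ colours into species profiles
#'
#' Each photograph contributes one RGB measurement and one signal proportion
#' per visible organ.  Across photographs of a species, each organ's colour
#' becomes the unweighted mean (the organ "centroid") over the photos in which
#' it was measured, and its weight the mean of its measured proportions,
#' renormalised so that the per-species weights sum to exactly 1.
#'
#' @param rows Data frame with columns `species`, `photo_id`, `organ`, `R`,
#'   `G`, `B`, `proportion`; within each photo, proportions must sum to 1
#'   (deviations above 0.05 are an error).
#' @return A [color_profile].
#' @export
aggregate_profile <- function(rows) {
  need <- c("species", "photo_id", "organ", "R", "G", "B", "proportion")
  if (!all(need %in% names(rows)))
    stop("need columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!nrow(rows)) stop("no colour rows supplied", call. = FALSE)
  key <- interaction(rows$species, rows$photo_id, drop = TRUE)
  psum <- tapply(rows$proportion, key, sum)
  if (any(abs(psum - 1) > 0.05))
    stop("per-photo organ proportions must sum to 1 (tolerance 0.05); off for ",
         paste(names(psum)[abs(psum - 1) > 0.05], collapse = ", "), call. = FALSE)
  agg <- stats::aggregate(rows[, c("R", "G", "B", "proportion")],
                          by = list(species = rows$species, organ = rows$organ),
                          FUN = mean)
  agg <- agg[order(agg$species, agg$organ), ]
  wsum <- stats::ave(agg$proportion, agg$species, FUN = sum)
  color_profile(data.frame(species = agg$species, organ = agg$organ,
                           R = agg$R, G = agg$G, B = agg$B,
                           weight = agg$proportion / wsum))
}

#' @rdname aggregate_profile
#' @param path CSV with the columns listed for `rows`.
#' @export
read_color_rows <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# ---- exact transportation problem ------------------------------------------

# Solve min sum(F * C) s.t. rowSums(F) = a, colSums(F) = b, F >= 0, by the
# transportation simplex (north-west-corner start, u-v duals, cycle pivots).
# Degeneracy is broken by an epsilon perturbation of the supplies; the flows
# on the final optimal basis are then re-solved against the unperturbed
# margins, so the returned cost is exact.
.transport_solve <- function(a, b, C, max_iter = 10000L) {
  m <- length(a); n <- length(b)
  stopifnot(nrow(C) == m, ncol(C) == n)
  if (abs(sum(a) - sum(b)) > 1e-8 * max(sum(a), sum(b)))
    stop("transportation margins must balance", call. = FALSE)
  a <- a / sum(a); b <- b / sum(b)
  if (m == 1L) return(list(cost = sum(b * C[1, ]), plan = matrix(b, 1L, n)))
  if (n == 1L) return(list(cost = sum(a * C[, 1]), plan = matrix(a, m, 1L)))

  eps <- 1e-11
  ap <- a + eps
  bp <- b; bp[n] <- bp[n] + m * eps

  FL <- matrix(0, m, n)          # flows
  BA <- matrix(FALSE, m, n)      # basis membership
  ar <- ap; br <- bp
  i <- 1L; j <- 1L
  repeat {                       # north-west corner rule
    f <- min(ar[i], br[j])
    FL[i, j] <- f; BA[i, j] <- TRUE
    ar[i] <- ar[i] - f; br[j] <- br[j] - f
    if (i == m && j == n) break
    if (i < m && ar[i] < br[j]) i <- i + 1L else j <- j + 1L
  }

  ctol <- 1e-12 * (1 + max(abs(C)))
  for (iter in seq_len(max_iter)) {
    # duals by propagation over the basis tree
    u <- rep(NA_real_, m); v <- rep(NA_real_, n)
    u[1L] <- 0
    bcells <- which(BA, arr.ind = TRUE)
    repeat {
      progressed <- FALSE
      for (r in seq_len(nrow(bcells))) {
        bi <- bcells[r, 1L]; bj <- bcells[r, 2L]
        if (!is.na(u[bi]) && is.na(v[bj])) { v[bj] <- C[bi, bj] - u[bi]; progressed <- TRUE }
        else if (is.na(u[bi]) && !is.na(v[bj])) { u[bi] <- C[bi, bj] - v[bj]; progressed <- TRUE }
      }
      if (!progressed) break
    }
    u[is.na(u)] <- 0; v[is.na(v)] <- 0    # disconnected forest guard

    red <- C - outer(u, v, "+")
    red[BA] <- Inf
    enter <- arrayInd(which.min(red), dim(red))
    if (red[enter] >= -ctol) break

    ei <- enter[1L]; ej <- enter[2L]
    # unique path row-node ei -> col-node ej through the basis tree (BFS)
    nn <- m + n
    parent <- integer(nn); parent_cell <- matrix(0L, nn, 2L)
    visited <- logical(nn); visited[ei] <- TRUE
    queue <- ei
    while (length(queue)) {
      node <- queue[1L]; queue <- queue[-1L]
      if (node <= m) {
        for (jj in which(BA[node, ])) {
          cn <- m + jj
          if (!visited[cn]) {
            visited[cn] <- TRUE; parent[cn] <- node
            parent_cell[cn, ] <- c(node, jj); queue <- c(queue, cn)
          }
        }
      } else {
        jj <- node - m
        for (ii in which(BA[, jj])) {
          if (!visited[ii]) {
            visited[ii] <- TRUE; parent[ii] <- node
            parent_cell[ii, ] <- c(ii, jj); queue <- c(queue, ii)
          }
        }
      }
    }
    if (!visited[m + ej]) stop("degenerate transportation basis", call. = FALSE)
    path <- list(); node <- m + ej
    while (node != ei) {
      path[[length(path) + 1L]] <- parent_cell[node, ]
      node <- parent[node]
    }
    path <- rev(path)  # cells from the ei end towards ej
    sgn <- rep_len(c(-1, 1), length(path))
    minus <- which(sgn < 0)
    flows <- vapply(path[minus], function(cl) FL[cl[1L], cl[2L]], numeric(1))
    k <- minus[which.min(flows)]
    theta <- min(flows)
    for (s in seq_along(path)) {
      cl <- path[[s]]
      FL[cl[1L], cl[2L]] <- FL[cl[1L], cl[2L]] + sgn[s] * theta
    }
    leave <- path[[k]]
    BA[leave[1L], leave[2L]] <- FALSE
    FL[leave[1L], leave[2L]] <- 0
    BA[ei, ej] <- TRUE
    FL[ei, ej] <- theta
  }

  # re-solve flows on the optimal basis against the unperturbed margins by
  # leaf peeling on the basis tree
  FL2 <- matrix(0, m, n)
  B2 <- BA
  ar <- a; br <- b
  repeat {
    nb <- sum(B2)
    if (!nb) break
    ri <- which(rowSums(B2) == 1L)
    if (length(ri)) {
      ii <- ri[1L]; jj <- which(B2[ii, ])[1L]
      f <- ar[ii]
    } else {
      cj <- which(colSums(B2) == 1L)
      if (!length(cj)) break
      jj <- cj[1L]; ii <- which(B2[, jj])[1L]
      f <- br[jj]
    }
    FL2[ii, jj] <- f
    ar[ii] <- ar[ii] - f; br[jj] <- br[jj] - f
    B2[ii, jj] <- FALSE
  }
  FL2[FL2 < 0] <- 0
  list(cost = sum(FL2 * C), plan = FL2)
}

.as_pointset <- function(p) {
  if (is.list(p) && !is.data.frame(p) && all(c("points", "weights") %in% names(p)))
    return(list(points = as.matrix(p$points), weights = as.numeric(p$weights)))
  if (is.data.frame(p) && all(c("R", "G", "B", "weight") %in% names(p)))
    return(list(points = as.matrix(p[, c("R", "G", "B")]),
                weights = as.numeric(p$weight)))
  stop("cannot interpret colour point set; give list(points, weights) or a profile entry",
       call. = FALSE)
}

#' Earth-mover's distance between two colour profiles
#'
#' Minimal mass-transport cost between two weighted colour point sets, with
#' Euclidean RGB distance as the ground metric.  The transportation linear
#' program is solved to optimality (profiles have at most a handful of organ
#' centroids, so the exact simplex is cheap).  This captures both how
#' different two species' colours are and how much of the floral signal each
#' colour occupies.
#'
#' @param p,q Profile entries (see [profile_entry()]) or lists with elements
#'   `points` (rows = colour points) and `weights`.
#' @param tol Tolerance for the weight normalisation check.
#' @return Nonnegative scalar distance.
#' @export
emd <- function(p, q, tol = 1e-6) {
  p <- .as_pointset(p); q <- .as_pointset(q)
  if (abs(sum(p$weights) - 1) > tol || abs(sum(q$weights) - 1) > tol)
    stop("profile weights must sum to 1", call. = FALSE)
  xp <- p$points; xq <- q$points
  # explicit per-channel differences: no cancellation for coincident points
  C2 <- 0
  for (ch in seq_len(ncol(xp))) C2 <- C2 + outer(xp[, ch], xq[, ch], "-")^2
  C <- sqrt(C2)
  .transport_solve(p$weights / sum(p$weights), q$weights / sum(q$weights), C)$cost
}

#' Pairwise chromatic distance matrix
#'
#' Earth-mover's distances between all pairs of species colour profiles.
#'
#' @param profile A [color_profile].
#' @return A symmetric matrix with species dimnames and attribute
#'   `metric = "earth-mover, Euclidean ground distance in RGB"`.
#' @export
color_distance_matrix <- function(profile) {
  spp <- unique(profile$species)
  if (length(spp) < 2) stop("need at least two species", call. = FALSE)
  entries <- lapply(spp, profile_entry, profile = profile)
  n <- length(spp)
  D <- matrix(0, n, n, dimnames = list(spp, spp))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      D[i, j] <- D[j, i] <- emd(entries[[i]], entries[[j]])
    }
  }
  attr(D, "metric") <- "earth-mover, Euclidean ground distance in RGB"
  D
}

#' @rdname color_distance_matrix
#' @param D A square distance matrix with dimnames.
#' @param path Output CSV path (header row and first column give species).
#' @export
write_color_distances <- function(D, path) {
  utils::write.csv(data.frame(species = rownames(D), D, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(D)
}

#' First principal component of organ colours
#'
#' PCA on a species-by-RGB matrix for one organ class; returns the PC1 scores
#' (used for phylogenetic signal tests when PC1 explains most colour
#' variation) with the sign convention that the red-channel loading is
#' non-negative.
#'
#' @param values Species x 3 matrix of RGB values (rownames = species).
#' @return List with `scores` (named vector), `varexp` (fraction of variance
#'   on PC1) and `loadings`.
#' @export
pca_first_pc <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 3) stop("need at least three species for PCA", call. = FALSE)
  if (all(apply(values, 2, stats::var) < 1e-300))
    stop("zero colour variance", call. = FALSE)
  pc <- stats::prcomp(values, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, 1]
  flip <- if (abs(rot[1]) > 0) sign(rot[1]) else 1
  if (flip == 0) flip <- 1
  scores <- pc$x[, 1] * flip
  names(scores) <- rownames(values)
  list(scores = scores,
       varexp = pc$sdev[1]^2 / sum(pc$sdev^2),
       loadings = rot * flip)
}

#' Principal coordinate embedding of a distance matrix
#'
#' Classical scaling (Torgerson): eigen-decomposition of the double-centred
#' -D^2/2 matrix.  Negative eigenvalues (the matrix need not be Euclidean) are
#' truncated to zero with a warning; variance-explained fractions are taken
#' over the positive eigenvalues.
#'
#' @param D Symmetric distance matrix with species dimnames.
#' @param k Number of axes to keep (k < number of species).
#' @return List of class `pcoa_embedding` with `coords` (species x k),
#'   `eigenvalues` and `varexp` (nonincreasing fractions in `[0,1]`).
#' @export
pcoa_embed <- function(D, k = 5) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k <= n - 1", call. = FALSE)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  if (any(ev < -1e-8 * max(abs(ev), 1)))
    warning("negative eigenvalues truncated to zero (non-Euclidean distances)",
            call. = FALSE)
  ev[ev < 0] <- 0
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev[seq_len(k)]), k)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("A", seq_len(k))
  tot <- sum(ev)
  structure(list(coords = coords, eigenvalues = ev,
                 varexp = if (tot > 0) ev[seq_len(k)] / tot else rep(0, k)),
            class = "pcoa_embedding")
}

#' @export
print.pcoa_embedding <- function(x, ...) {
  cat("PCoA embedding:", nrow(x$coords), "species x", ncol(x$coords), "axes;",
      sprintf("variance explained %.1f%%\n", 100 * sum(x$varexp)))
  invisible(x)
}
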