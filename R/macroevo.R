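# Phylogenetic signal, trait-evolution model selection, disparity through
# time and lineage-through-time curves.

.align_trait <- function(tree, x) {
  if (!is.null(names(x))) {
    miss <- setdiff(tree$tip.label, names(x))
    if (length(miss)) stop("trait values missing for: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    x <- x[tree$tip.label]
  } else if (length(x) != ape::Ntip(tree)) {
    stop("trait length does not match the number of tips", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("trait values must be finite", call. = FALSE)
  as.numeric(x)
}

#' Blomberg's K
#'
#' Ratio-based phylogenetic signal statistic scaled so that K = 1 is the
#' Brownian-motion expectation on the given tree.  The observed ratio of the
#' mean squared error around the phylogenetic (GLS) mean to the
#' phylogenetically corrected mean squared error is divided by its analytic
#' BM expectation; the p-value is the fraction of tip-label permutations
#' whose ratio is at least the observed one (observed permutation included).
#'
#' @param tree Dated `phylo` with at least 4 tips.
#' @param x Named (or tip-ordered) numeric trait vector with nonzero
#'   variance.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return List with `K`, `p.value`, `n_perm`.
#' @export
blomberg_k <- function(tree, x, n_perm = 999, seed = NULL) {
  x <- .align_trait(tree, x)
  n <- length(x)
  if (n < 4) stop("need at least 4 tips", call. = FALSE)
  if (stats::var(x) <= 0) stop("trait has zero variance", call. = FALSE)
  C <- ape::vcv(tree)
  ch <- chol(C)
  one <- rep(1, n)
  Ci_one <- backsolve(ch, backsolve(ch, one, transpose = TRUE))
  s_Ci <- sum(Ci_one)
  ratio <- function(xv) {
    ahat <- sum(Ci_one * xv) / s_Ci
    r <- xv - ahat
    z <- backsolve(ch, r, transpose = TRUE)
    sum(r * r) / sum(z * z)
  }
  obs <- ratio(x)
  expected <- (sum(diag(C)) - n / s_Ci) / (n - 1)
  K <- obs / expected
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) ratio(sample(x)), numeric(1))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(K = K, p.value = p, n_perm = n_perm)
}

#' Pagel's lambda
#'
#' Maximum-likelihood multiplier on the off-diagonal phylogenetic covariance,
#' constrained to `[0, 1]`: 0 collapses the tree to a star (no signal), 1
#' recovers Brownian motion.  The p-value is a likelihood-ratio test against
#' lambda = 0 on one degree of freedom.
#'
#' @inheritParams blomberg_k
#' @return List with `lambda`, `loglik`, `loglik0`, `p.value`.
#' @export
pagel_lambda <- function(tree, x) {
  x <- .align_trait(tree, x)
  if (length(x) < 4) stop("need at least 4 tips", call. = FALSE)
  C <- ape::vcv(tree)
  dC <- diag(C)
  lik <- function(lam) {
    Cl <- C * lam
    diag(Cl) <- dC
    .gls_profile(x, Cl)$loglik
  }
  opt <- stats::optimize(lik, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, lik(0), lik(1))
  best <- which.max(lls)
  lambda <- cand[best]; ll1 <- lls[best]
  ll0 <- lik(0)
  if (!is.finite(ll1)) stop("non-finite likelihood", call. = FALSE)
  p <- stats::pchisq(2 * (ll1 - ll0), df = 1, lower.tail = FALSE)
  list(lambda = lambda, loglik = ll1, loglik0 = ll0, p.value = p)
}

#' Small-sample Akaike information criterion
#' @param lnL Log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (number of tips).
#' @export
aicc <- function(lnL, k, n) {
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit BM, OU and white-noise models of trait evolution
#'
#' Maximum-likelihood fits of three classic single-trait models on a dated
#' (ultrametric) tree: Brownian motion (stochastic drift; rate and root
#' state), single-optimum Ornstein-Uhlenbeck with the optimum at the root
#' state (constrained evolution; rate, attraction strength alpha, root) and
#' white noise (phylogeny-free iid; mean and variance).  Models are compared
#' by AICc and Akaike weights.
#'
#' @inheritParams blomberg_k
#' @param models Subset of `"BM"`, `"OU"`, `"WN"`.
#' @return Data frame of class `trait_model_fits` with columns `model`,
#'   `lnL`, `k`, `AICc`, `weight` and per-model parameter attributes.
#' @export
fit_trait_models <- function(tree, x, models = c("BM", "OU", "WN")) {
  models <- match.arg(models, several.ok = TRUE)
  x <- .align_trait(tree, x)
  n <- length(x)
  if (n < 4) stop("need at least 4 tips", call. = FALSE)
  C <- ape::vcv(tree)
  Tht <- max(diag(C))
  D <- patristic_distances(tree)[rownames(C), colnames(C)]
  fits <- list()
  if ("BM" %in% models) {
    g <- .gls_profile(x, C)
    fits$BM <- list(model = "BM", lnL = g$loglik, k = 2,
                    pars = c(sigma2 = g$s2, root = g$mu))
  }
  if ("OU" %in% models) {
    ou_ll <- function(la) {
      a <- exp(la)
      Vs <- (1 - exp(-2 * a * C)) * exp(-a * D) / (2 * a)
      .gls_profile(x, Vs)$loglik
    }
    opt <- stats::optimize(ou_ll, c(log(1e-9 / Tht), log(50 / Tht)),
                           maximum = TRUE, tol = 1e-8)
    a <- exp(opt$maximum)
    Vs <- (1 - exp(-2 * a * C)) * exp(-a * D) / (2 * a)
    g <- .gls_profile(x, Vs)
    if (!is.finite(g$loglik))
      stop("OU optimisation did not converge to a finite likelihood", call. = FALSE)
    fits$OU <- list(model = "OU", lnL = g$loglik, k = 3,
                    pars = c(sigma2 = g$s2, alpha = a, root = g$mu))
  }
  if ("WN" %in% models) {
    mu <- mean(x)
    s2 <- mean((x - mu)^2)
    ll <- sum(stats::dnorm(x, mu, sqrt(s2), log = TRUE))
    fits$WN <- list(model = "WN", lnL = ll, k = 2,
                    pars = c(mean = mu, sigma2 = s2))
  }
  tab <- data.frame(model = vapply(fits, `[[`, "", "model"),
                    lnL = vapply(fits, `[[`, 0, "lnL"),
                    k = vapply(fits, `[[`, 0, "k"))
  tab$AICc <- aicc(tab$lnL, tab$k, n)
  w <- exp(-0.5 * (tab$AICc - min(tab$AICc)))
  tab$weight <- w / sum(w)
  attr(tab, "pars") <- lapply(fits, `[[`, "pars")
  class(tab) <- c("trait_model_fits", "data.frame")
  tab
}

#' @export
print.trait_model_fits <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# mean squared pairwise Euclidean distance among rows (0 for a single row)
.disparity <- function(D2sub) {
  n <- nrow(D2sub)
  if (n < 2) return(0)
  sum(D2sub[upper.tri(D2sub)]) / (n * (n - 1) / 2)
}

# crossing clades (tip index sets) at each internal-node height, root first
.dtt_clades <- function(tree) {
  n <- ape::Ntip(tree)
  depths <- .node_depths(tree)
  internal <- seq.int(n + 1L, n + tree$Nnode)
  ord <- internal[order(depths[internal])]
  tips_below <- .tips_below(tree)
  pdep <- depths[tree$edge[, 1]]
  cdep <- depths[tree$edge[, 2]]
  clades <- vector("list", length(ord))
  times <- depths[ord]
  clades[[1]] <- list(seq_len(n))            # the whole clade at the root
  for (i in seq_along(ord)[-1]) {
    t <- times[i]
    crossing <- which(pdep <= t & cdep > t)
    clades[[i]] <- lapply(tree$edge[crossing, 2], function(v) tips_below[[v]])
  }
  list(times = times, clades = clades, tips_below = tips_below)
}

.dtt_curve <- function(X, clades_info) {
  D2 <- as.matrix(stats::dist(X))^2
  tot <- .disparity(D2)
  if (tot <= 0) return(rep(NA_real_, length(clades_info$clades)))
  vapply(clades_info$clades, function(cl) {
    mean(vapply(cl, function(tipset)
      .disparity(D2[tipset, tipset, drop = FALSE]), numeric(1))) / tot
  }, numeric(1))
}

#' Disparity through time with a Brownian-motion envelope
#'
#' At each internal-node height (root first), the mean relative disparity of
#' the subclades extant at that time: subclade mean squared pairwise trait
#' distance divided by the whole-clade disparity.  The observed curve is
#' compared to a pointwise 95\% envelope from multivariate BM simulations
#' whose rate matrix is estimated from the phylogenetic independent contrasts
#' of the data.  The MDI statistic (area between the observed curve and the
#' simulation median) is reported but carries no test.
#'
#' @param tree Ultrametric `phylo` with >= 3 tips.
#' @param X Tip values: vector or tips x k matrix (rownames = tip labels).
#' @param n_sims Number of BM simulations for the envelope (default 1000).
#' @param seed Optional integer seed.
#' @return Object of class `dtt_profile`: `times` (relative, 0 = root,
#'   1 = present), `disparity`, `lower`, `upper`, `sim_mean`, `mdi`,
#'   `n_sims`.
#' @export
dtt <- function(tree, X, n_sims = 1000, seed = NULL) {
  if (ape::Ntip(tree) < 3) stop("need at least 3 tips", call. = FALSE)
  X <- if (is.null(dim(X))) matrix(.align_trait(tree, X), ncol = 1,
                                   dimnames = list(tree$tip.label, "trait"))
       else as.matrix(X)[tree$tip.label, , drop = FALSE]
  info <- .dtt_clades(tree)
  obs <- .dtt_curve(X, info)
  if (anyNA(obs)) stop("whole-clade disparity is zero (degenerate traits)",
                       call. = FALSE)
  # BM rate matrix from the standardized independent contrasts
  tree_di <- ape::multi2di(tree, random = FALSE)
  pics <- apply(X, 2, function(col) ape::pic(col, tree_di))
  pics <- as.matrix(pics)
  R <- crossprod(pics) / nrow(pics)
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv(tree)
  cC <- chol(C)
  cR <- tryCatch(chol(R), error = function(e) {
    ev <- eigen(R, symmetric = TRUE)
    ev$values[ev$values < 1e-12 * max(ev$values)] <- 1e-12 * max(ev$values)
    chol(ev$vectors %*% diag(ev$values, nrow(R)) %*% t(ev$vectors))
  })
  n <- nrow(X); p <- ncol(X)
  sims <- matrix(NA_real_, n_sims, length(obs))
  for (s in seq_len(n_sims)) {
    Z <- matrix(stats::rnorm(n * p), n, p)
    Xs <- t(cC) %*% Z %*% cR
    rownames(Xs) <- tree$tip.label
    sims[s, ] <- .dtt_curve(Xs, info)
  }
  lo <- matrixStats::colQuantiles(sims, probs = 0.025)
  hi <- matrixStats::colQuantiles(sims, probs = 0.975)
  med <- colMeans(sims)
  Tht <- .tree_height(tree)
  structure(list(times = info$times / Tht, disparity = obs,
                 lower = lo, upper = hi, sim_mean = med,
                 mdi = mean(obs - med), n_sims = n_sims),
            class = "dtt_profile")
}

#' @export
print.dtt_profile <- function(x, ...) {
  inside <- mean(x$disparity >= x$lower & x$disparity <= x$upper)
  cat(sprintf("DTT over %d node times; inside the %d-sim 95%% BM envelope at %.0f%% of times; MDI = %.3f\n",
              length(x$times), x$n_sims, 100 * inside, x$mdi))
  invisible(x)
}

#' Lineages through time
#'
#' Step counts of reconstructed lineages from the root (1 lineage) to the
#' present (n tips), with the constant-rate expectation (log-linear between 2
#' lineages at the root divergence and n at the present).
#'
#' @param tree Dated `phylo`.
#' @return List with `time` (from the root), `n_lineages`, and `expectation`
#'   (same times, log-linear null).
#' @export
ltt <- function(tree) {
  n <- ape::Ntip(tree)
  depths <- .node_depths(tree)
  internal <- seq.int(n + 1L, n + tree$Nnode)
  # each internal node of out-degree c adds c - 1 lineages at its height
  deg <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)[internal]
  ord <- order(depths[internal])
  tm <- depths[internal][ord]
  inc <- (deg - 1)[ord]
  counts <- 1 + cumsum(inc)
  Tht <- .tree_height(tree)
  expectation <- 2 * (n / 2)^(tm / Tht)
  list(time = tm, n_lineages = counts, expectation = expectation,
       present = c(time = Tht, n_lineages = n))
}
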