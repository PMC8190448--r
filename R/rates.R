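# Branch-specific trait-evolution rates, diversification-rate proxies and
# the phylogenetic mixed-model regression of log trait rate on
# diversification rate and branch age.

#' Branch-specific trait rates by phylogenetic ridge regression
#'
#' Decomposes the tip values into per-edge phenotypic changes delta by
#' penalised least squares: minimise `||x0 - A delta||^2 + penalty *
#' ||delta||^2`, where `A` is the tips x edges root-to-tip path incidence
#' matrix and `x0` the tip values centred on the GLS root estimate.  The
#' per-edge evolutionary rate is `|delta| / branch length`.  When `penalty`
#' is `NULL` it is chosen by generalised cross-validation over a fixed
#' logarithmic grid (`10^-4 .. 10^4`, 25 points); `penalty = 0` returns the
#' minimum-norm least-squares solution.
#'
#' @param tree Ultrametric dated `phylo` (>= 4 tips).
#' @param x Named tip trait vector.
#' @param penalty Ridge penalty (>= 0) or `NULL` for GCV selection.
#' @return Data frame with one row per edge: `edge`, `parent`, `child`,
#'   `length`, `delta`, `rate` (NA with a warning for zero-length edges);
#'   attributes `penalty` and `root_state`.
#' @export
ridge_rates <- function(tree, x, penalty = NULL) {
  x <- .align_trait(tree, x)
  n <- length(x)
  if (n < 2) stop("need at least 2 tips", call. = FALSE)
  if (!is_ultrametric(tree))
    stop("ridge rates assume an ultrametric dated tree", call. = FALSE)
  A <- .edge_incidence(tree)
  C <- ape::vcv(tree)
  ch <- chol(C)
  one <- rep(1, n)
  Ci_one <- backsolve(ch, backsolve(ch, one, transpose = TRUE))
  root <- sum(Ci_one * x) / sum(Ci_one)
  x0 <- x - root
  sv <- svd(A)
  d <- sv$d
  uy <- crossprod(sv$u, x0)
  if (is.null(penalty)) {
    grid <- 10^seq(-4, 4, length.out = 25)
    gcv <- vapply(grid, function(lam) {
      shrink <- d^2 / (d^2 + lam)
      rss <- sum(((1 - shrink) * uy)^2)   # residual lies in span(U) here
      trH <- sum(shrink)
      n * rss / (n - trH)^2
    }, numeric(1))
    penalty <- grid[which.min(gcv)]
  }
  if (penalty < 0) stop("penalty must be >= 0", call. = FALSE)
  if (penalty == 0) {
    pos <- d > max(d) * 1e-12
    delta <- sv$v[, pos, drop = FALSE] %*% (uy[pos] / d[pos])
  } else {
    delta <- sv$v %*% (d * uy / (d^2 + penalty))
  }
  delta <- as.numeric(delta)
  len <- tree$edge.length
  rate <- abs(delta) / len
  if (any(len == 0)) {
    warning("zero-length edges: rate undefined (NA)", call. = FALSE)
    rate[len == 0] <- NA_real_
  }
  out <- data.frame(edge = seq_len(nrow(tree$edge)),
                    parent = tree$edge[, 1], child = tree$edge[, 2],
                    length = len, delta = delta, rate = rate)
  attr(out, "penalty") <- penalty
  attr(out, "root_state") <- root
  out
}

#' Tip DR statistic and per-edge diversification-rate proxy
#'
#' The DR (inverse equal-splits) statistic for tip i is `1 / ES_i` with
#' `ES_i = sum_j l_j * 2^-(j-1)` over the edges from the tip (j = 1) back to
#' the root: recent rapid branching yields short tipward edges, small ES and
#' a high rate.  The per-edge proxy is the mean DR of the edge's descendant
#' tips.  This is a deterministic stand-in for branch-specific diversification
#' rates; externally estimated per-edge rates (e.g. from a Bayesian
#' diversification model) can be supplied downstream instead.
#'
#' @param tree Dated `phylo`.
#' @return Numeric vector of per-edge rates (tree$edge order), with the
#'   per-tip DR statistic as attribute `tip_dr`.
#' @export
div_rate_proxy <- function(tree) {
  n <- ape::Ntip(tree)
  nnode <- tree$Nnode
  parent_edge <- integer(n + nnode)          # edge leading into each node
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  es <- numeric(n)
  for (i in seq_len(n)) {
    node <- i; j <- 0L; acc <- 0
    while (parent_edge[node] != 0L) {
      e <- parent_edge[node]
      acc <- acc + tree$edge.length[e] * 2^(-j)
      j <- j + 1L
      node <- tree$edge[e, 1]
    }
    es[i] <- acc
  }
  dr <- 1 / es
  names(dr) <- tree$tip.label
  tb <- .tips_below(tree)
  edge_rate <- vapply(seq_len(nrow(tree$edge)),
                      function(e) mean(dr[tb[[tree$edge[e, 2]]]]), numeric(1))
  attr(edge_rate, "tip_dr") <- dr
  edge_rate
}

#' Assemble the per-branch rate table
#'
#' One row per edge of the tree, carrying the trait-evolution rate, the
#' diversification-rate proxy and the branch age (root-to-child-node
#' distance); rates are associated with the edge's child node for the
#' phylogenetic covariance of the regression.
#'
#' @param tree Dated `phylo`.
#' @param trait_rates Per-edge rates, e.g. `ridge_rates(tree, x)$rate`.
#' @param div_rates Per-edge diversification rates, e.g.
#'   [div_rate_proxy()]; any externally computed per-edge vector in
#'   `tree$edge` order is accepted.
#' @return Data frame of class `branch_rate_table` with columns `edge`,
#'   `child`, `branch_age`, `trait_rate`, `div_rate`.
#' @export
branch_rate_table <- function(tree, trait_rates, div_rates) {
  ne <- nrow(tree$edge)
  stopifnot(length(trait_rates) == ne, length(div_rates) == ne)
  if (any(!is.finite(div_rates)) || any(div_rates <= 0))
    stop("diversification rates must be positive", call. = FALSE)
  if (any(trait_rates < 0, na.rm = TRUE))
    stop("trait rates must be >= 0", call. = FALSE)
  depths <- .node_depths(tree)
  out <- data.frame(edge = seq_len(ne),
                    child = tree$edge[, 2],
                    branch_age = depths[tree$edge[, 2]],
                    trait_rate = as.numeric(trait_rates),
                    div_rate = as.numeric(div_rates))
  class(out) <- c("branch_rate_table", "data.frame")
  out
}

#' Dominant colour per species
#'
#' The single RGB value making up the largest proportion of the inflorescence
#' colour signal (the organ with maximum weight; ties broken by organ-name
#' order).
#'
#' @param profile A [color_profile].
#' @return Species x 3 RGB matrix.
#' @export
dominant_color <- function(profile) {
  spp <- unique(profile$species)
  out <- t(vapply(spp, function(s) {
    rows <- profile[profile$species == s, , drop = FALSE]
    rows <- rows[order(-rows$weight, rows$organ), , drop = FALSE]
    as.numeric(rows[1, c("R", "G", "B")])
  }, numeric(3)))
  dimnames(out) <- list(spp, c("R", "G", "B"))
  out
}

#' Weakly informative prior scale from BM contrasts
#'
#' Estimates the Brownian-motion standard deviation of regression residuals
#' as the square root of the mean squared standardized phylogenetic
#' independent contrast, and returns the rate of an exponential prior placing
#' 1\% of its mass above three times that estimate:
#' `rate = -log(0.01) / (3 s)`.
#'
#' @param tree Dated `phylo`.
#' @param residuals Residuals named by tip label (entries for internal nodes,
#'   if present, are ignored: contrasts are defined on tip values).
#' @return List with `s` (BM sd estimate), `s2`, and `rate` of the
#'   exponential prior.
#' @export
bm_prior_sd <- function(tree, residuals) {
  res <- residuals[names(residuals) %in% tree$tip.label]
  if (length(res) < 3) stop("need residuals at >= 3 tips (>= 2 contrasts)",
                            call. = FALSE)
  tr <- if (length(res) < ape::Ntip(tree)) prune_to_samples(tree, names(res)) else tree
  pic <- ape::pic(res[tr$tip.label], ape::multi2di(tr, random = FALSE))
  s2 <- mean(pic^2)
  s <- sqrt(s2)
  list(s = s, s2 = s2, rate = -log(0.01) / (3 * s))
}

# Integrated (flat-beta) Gaussian log-likelihood for y = X b + u + e,
# V = sp2 * C + se2 * I.  Returns loglik plus the conditional beta posterior.
.integrated_loglik <- function(y, X, C, sp2, se2) {
  n <- length(y); p <- ncol(X)
  V <- sp2 * C
  diag(V) <- diag(V) + se2
  chV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(chV)) return(list(loglik = -Inf))
  Xi <- backsolve(chV, X, transpose = TRUE)
  yi <- backsolve(chV, y, transpose = TRUE)
  XtVX <- crossprod(Xi)
  chB <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chB)) return(list(loglik = -Inf))
  beta <- backsolve(chB, backsolve(chB, crossprod(Xi, yi), transpose = TRUE))
  r <- yi - Xi %*% beta
  ll <- -0.5 * (n - p) * log(2 * pi) - sum(log(diag(chV))) -
    sum(log(diag(chB))) - 0.5 * sum(r * r)
  list(loglik = ll, beta = as.numeric(beta), cov_beta = chol2inv(chB))
}

#' Phylogenetic mixed-model regression of branch rates
#'
#' Fits `log(trait_rate + 0.1) ~ predictors` across branches with a
#' phylogenetic random effect at the branch's child node: `y = X beta + u +
#' e`, `cov(u) = sigma_p^2 C` where `C_ij` is the shared root-to-node path
#' length between child nodes (internal and terminal alike), `e` iid.  The
#' predictors are the log diversification rate (`log(div_rate + 0.1)`) and
#' the branch age, each standardized.  Fixed effects carry a flat prior and
#' are integrated analytically; the two standard deviations get exponential
#' priors (the phylogenetic one from [bm_prior_sd()] on the OLS residuals
#' unless supplied) and are optimised to their posterior mode, with the log
#' marginal likelihood from a Laplace approximation at that mode.  This is a
#' deliberate single-Laplace stand-in for a full nested-Laplace Bayesian fit;
#' Bayes factors inherit the approximation.
#'
#' @param rates A [branch_rate_table].
#' @param predictors Subset of `"divrate"`, `"age"` (empty = intercept-only).
#' @param tree The dated `phylo` the table was built from.
#' @param prior Optional list with `rate_p` and/or `rate_e` (exponential
#'   prior rates for the phylogenetic and residual sd).
#' @param log_age Also log-transform branch age before standardizing
#'   (default `FALSE`: age is standardized untransformed).
#' @param sigma_p Fix the phylogenetic sd (e.g. `0` for an ordinary
#'   regression) instead of estimating it.
#' @return Object of class `rate_regression_fit`: `coefficients` (estimate
#'   and 95\% credible interval), `sigma_p`, `sigma_e`, `logML`, `prior`,
#'   `predictors`.
#' @export
rate_regression <- function(rates, predictors = c("divrate", "age"), tree,
                            prior = NULL, log_age = FALSE, sigma_p = NULL) {
  stopifnot(inherits(rates, "branch_rate_table"))
  if (length(predictors))
    predictors <- match.arg(predictors, c("divrate", "age"), several.ok = TRUE)
  if (anyNA(rates$trait_rate))
    stop("trait rates contain NA (zero-length edges?)", call. = FALSE)
  y <- log(rates$trait_rate + 0.1)
  X <- matrix(1, nrow(rates), 1, dimnames = list(NULL, "(Intercept)"))
  if ("divrate" %in% predictors)
    X <- cbind(X, divrate = as.numeric(scale(log(rates$div_rate + 0.1))))
  if ("age" %in% predictors) {
    age <- if (log_age) log(rates$branch_age) else rates$branch_age
    X <- cbind(X, age = as.numeric(scale(age)))
  }
  if (qr(X)$rank < ncol(X)) stop("singular design matrix", call. = FALSE)
  C <- .shared_depth_matrix(tree, rates$child)
  C <- C / mean(diag(C))          # unit average variance: sigma_p on y's scale
  n <- length(y)

  ols <- stats::lm.fit(X, y)
  res <- ols$residuals
  tipres <- res[rates$child <= ape::Ntip(tree)]
  names(tipres) <- tree$tip.label[rates$child[rates$child <= ape::Ntip(tree)]]
  # bm_prior_sd works per unit sqrt(time); rescale to the unit-diagonal C,
  # on which sigma_p is the sd of the random effect at an average-depth node
  md <- mean(diag(.shared_depth_matrix(tree, rates$child)))
  rate_p <- if (!is.null(prior$rate_p)) prior$rate_p else
    bm_prior_sd(tree, tipres)$rate / sqrt(md)
  rate_e <- if (!is.null(prior$rate_e)) prior$rate_e else
    -log(0.01) / (3 * stats::sd(res))

  logpost <- function(theta, fixed_sp = NULL) {
    if (is.null(fixed_sp)) {
      sp <- exp(theta[1]); se <- exp(theta[2])
      lp <- stats::dexp(sp, rate_p, log = TRUE) + log(sp) +
            stats::dexp(se, rate_e, log = TRUE) + log(se)
    } else {
      sp <- fixed_sp; se <- exp(theta[1])
      lp <- stats::dexp(se, rate_e, log = TRUE) + log(se)
    }
    .integrated_loglik(y, X, C, sp^2, se^2)$loglik + lp
  }

  s0 <- stats::sd(res)
  if (is.null(sigma_p)) {
    init <- log(c(s0 / 2, s0 / sqrt(2)))
    opt <- stats::optim(init, logpost, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = 2000, reltol = 1e-10))
    if (opt$convergence != 0)
      stop("posterior-mode optimisation did not converge", call. = FALSE)
    theta <- opt$par
    sp_hat <- exp(theta[1]); se_hat <- exp(theta[2])
    H <- stats::optimHess(theta, logpost)
    dpar <- 2L
  } else {
    opt <- stats::optimize(function(t) logpost(t, fixed_sp = sigma_p),
                           c(log(s0) - 10, log(s0) + 5), maximum = TRUE)
    theta <- opt$maximum
    sp_hat <- sigma_p; se_hat <- exp(theta)
    H <- stats::optimHess(theta, logpost, fixed_sp = sigma_p)
    dpar <- 1L
  }
  detH <- det(as.matrix(-H))
  if (!is.finite(detH) || detH <= 0) detH <- NA_real_
  lmax <- if (is.null(sigma_p)) opt$value else opt$objective
  logML <- lmax + 0.5 * dpar * log(2 * pi) -
    0.5 * (if (is.na(detH)) 0 else log(detH))

  fit <- .integrated_loglik(y, X, C, sp_hat^2, se_hat^2)
  se_beta <- sqrt(diag(as.matrix(fit$cov_beta)))
  coefs <- data.frame(term = colnames(X), estimate = fit$beta,
                      lower = fit$beta - 1.96 * se_beta,
                      upper = fit$beta + 1.96 * se_beta)
  structure(list(coefficients = coefs, sigma_p = sp_hat, sigma_e = se_hat,
                 logML = logML,
                 prior = list(rate_p = rate_p, rate_e = rate_e),
                 predictors = predictors,
                 fingerprint = c(n, round(sum(y), 10), round(sum(y^2), 10))),
            class = "rate_regression_fit")
}

#' @export
print.rate_regression_fit <- function(x, ...) {
  cat("Phylogenetic branch-rate regression (",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ")
      else "intercept only", ")\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 3)
  cat(sprintf("sigma_p = %.3g, sigma_e = %.3g, logML = %.3f\n",
              x$sigma_p, x$sigma_e, x$logML))
  invisible(x)
}

#' Bayes factor between two branch-rate regression fits
#'
#' `bf = exp(logML_a - logML_b)` with the conventional verbal scale: below
#' 3.2 the models are more or less equivalent, 3.2-10 a small to substantial
#' improvement, above 10 very strong.
#'
#' @param fit_a,fit_b [rate_regression()] fits on the same response data.
#' @return List with `bf` and `label`.
#' @export
bayes_factor <- function(fit_a, fit_b) {
  if (!isTRUE(all.equal(fit_a$fingerprint, fit_b$fingerprint)))
    stop("fits were not computed on the same response data", call. = FALSE)
  bf <- exp(fit_a$logML - fit_b$logML)
  label <- if (bf < 3.2) "equivalent"
           else if (bf <= 10) "small to substantial"
           else "very strong"
  list(bf = bf, label = label)
}
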