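# Internal numerical helpers shared across modules.

# Log-likelihood of r ~ N(0, V) via Cholesky; -Inf if V is not PD.
.mvn_loglik <- function(r, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * length(r) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z * z)
}

# Profiled Gaussian phylogenetic likelihood: x ~ N(mu * 1, s2 * C) with mu and
# s2 at their conditional ML.  Returns lnL, mu, s2.  C is the unit-rate
# covariance structure.
.gls_profile <- function(x, C) {
  n <- length(x)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf, mu = NA_real_, s2 = NA_real_))
  one <- rep(1, n)
  Ci_one <- backsolve(ch, backsolve(ch, one, transpose = TRUE))
  mu <- sum(Ci_one * x) / sum(Ci_one)
  r <- x - mu
  z <- backsolve(ch, r, transpose = TRUE)
  s2 <- sum(z * z) / n
  if (s2 <= 0) return(list(loglik = -Inf, mu = mu, s2 = s2))
  ll <- -0.5 * n * log(2 * pi) - 0.5 * n * log(s2) -
    sum(log(diag(ch))) - 0.5 * n
  list(loglik = ll, mu = mu, s2 = s2)
}

# Depth (distance from the root) of every node, tips first then internals,
# indexed as in tree$edge.
.node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

.tree_height <- function(tree) {
  max(.node_depths(tree)[seq_len(ape::Ntip(tree))])
}

# Shared root-to-node path length ("phylogenetic covariance") between
# arbitrary nodes (tips or internals).  nodes: vector of node ids.
.shared_depth_matrix <- function(tree, nodes) {
  h <- .node_depths(tree)
  D <- ape::dist.nodes(tree)
  S <- (outer(h[nodes], h[nodes], "+") - D[nodes, nodes, drop = FALSE]) / 2
  # guard tiny negative rounding on the diagonal path
  S[S < 0] <- 0
  dimnames(S) <- NULL
  S
}

# Explicit small determinants (hot path in FRic; avoids LAPACK call overhead).
.det_small <- function(M) {
  d <- nrow(M)
  if (d == 1L) return(M[1, 1])
  if (d == 2L) return(M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1])
  if (d == 3L) {
    return(M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
           M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
           M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1]))
  }
  det(M)
}

# Months in flower as an integer set, wrap-aware (e.g. Nov-Feb -> 11,12,1,2).
.months_in_flower <- function(start, end) {
  if (!is.finite(start) || !is.finite(end) ||
      start != round(start) || end != round(end) ||
      start < 1 || start > 12 || end < 1 || end > 12) {
    stop("flowering months must be integers in 1..12", call. = FALSE)
  }
  if (start <= end) seq.int(start, end) else c(seq.int(start, 12L), seq.int(1L, end))
}

# Tip indices descending from every node (list indexed by node id).
.tips_below <- function(tree) {
  n <- ape::Ntip(tree)
  res <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) res[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    res[[po$edge[e, 1]]] <- c(res[[po$edge[e, 1]]], res[[po$edge[e, 2]]])
  }
  res
}

# Tips x edges root-to-tip path incidence matrix (1 iff the edge lies on the
# path from the root to the tip); edges in tree$edge order.
.edge_incidence <- function(tree) {
  n <- ape::Ntip(tree)
  tb <- .tips_below(tree)
  A <- matrix(0, n, nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    A[tb[[tree$edge[e, 2]]], e] <- 1
  }
  rownames(A) <- tree$tip.label
  A
}

# Stable small-integer seeds derived from a master seed, staying below 2^31.
.child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 31L
}
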