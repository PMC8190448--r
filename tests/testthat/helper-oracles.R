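# Shared fixtures and independent oracles for the test suite.

tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

rand_profile <- function(n_pts) {
  w <- stats::runif(n_pts, 0.2, 1)
  list(points = matrix(stats::runif(3 * n_pts), ncol = 3),
       weights = w / sum(w))
}

# Brute-force transportation LP oracle: enumerate all basic solutions
# (subsets of m+n-1 cells), keep the feasible ones, take the minimum cost.
# Exact for small problems because an LP optimum sits at a vertex.
enum_transport_cost <- function(a, b, C) {
  m <- length(a); n <- length(b)
  a <- a / sum(a); b <- b / sum(b)
  cells <- as.matrix(expand.grid(i = seq_len(m), j = seq_len(n)))
  k <- m + n - 1L
  combs <- utils::combn(nrow(cells), k)
  best <- Inf
  for (ci in seq_len(ncol(combs))) {
    sel <- cells[combs[, ci], , drop = FALSE]
    A <- matrix(0, m + n, k)
    for (t in seq_len(k)) {
      A[sel[t, 1], t] <- 1
      A[m + sel[t, 2], t] <- 1
    }
    f <- tryCatch(solve(A[-(m + n), , drop = FALSE], c(a, b)[-(m + n)]),
                  error = function(e) NULL)
    if (is.null(f) || any(f < -1e-9)) next
    if (max(abs(A %*% f - c(a, b))) > 1e-9) next
    best <- min(best, sum(f * C[cbind(sel[, 1], sel[, 2])]))
  }
  best
}

# Run a python oracle: `script` reads one JSON object on stdin and prints one
# JSON object on stdout.  scipy/numpy are part of the runtime image.
run_py_oracle <- function(script, input) {
  infile <- tempfile(fileext = ".json")
  scfile <- tempfile(fileext = ".py")
  jsonlite::write_json(input, infile, auto_unbox = TRUE, digits = NA)
  writeLines(script, scfile)
  out <- suppressWarnings(
    system2("python", scfile, stdout = TRUE, stdin = infile))
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# scipy.linprog earth-mover oracle for a batch of profile pairs
py_emd_batch <- function(pairs) {
  script <- '
import sys, json
import numpy as np
from scipy.optimize import linprog
problems = json.load(sys.stdin)
res = []
for pr in problems:
    p = np.atleast_2d(np.array(pr["p"], dtype=float))
    q = np.atleast_2d(np.array(pr["q"], dtype=float))
    a = np.array(pr["a"], dtype=float); a = a / a.sum()
    b = np.array(pr["b"], dtype=float); b = b / b.sum()
    m, n = len(a), len(b)
    C = np.sqrt(((p[:, None, :] - q[None, :, :]) ** 2).sum(-1))
    Aeq = []
    for i in range(m):
        row = np.zeros((m, n)); row[i, :] = 1; Aeq.append(row.ravel())
    for j in range(n):
        row = np.zeros((m, n)); row[:, j] = 1; Aeq.append(row.ravel())
    r = linprog(C.ravel(), A_eq=np.array(Aeq)[:-1], b_eq=np.r_[a, b][:-1],
                bounds=(0, None), method="highs")
    res.append(r.fun)
print(json.dumps(res))
'
  as.numeric(run_py_oracle(script, pairs))
}

# scipy convex-hull volume oracle
py_hull_volumes <- function(point_sets) {
  script <- '
import sys, json
import numpy as np
from scipy.spatial import ConvexHull
sets = json.load(sys.stdin)
out = []
for s in sets:
    P = np.array(s, dtype=float)
    out.append(float(ConvexHull(P).volume))
print(json.dumps(out))
'
  as.numeric(run_py_oracle(script, point_sets))
}

# numpy minimum-norm least squares oracle
py_lstsq <- function(A, y) {
  script <- '
import sys, json
import numpy as np
d = json.load(sys.stdin)
A = np.array(d["A"], dtype=float)
y = np.array(d["y"], dtype=float)
x, *_ = np.linalg.lstsq(A, y, rcond=None)
print(json.dumps(x.tolist()))
'
  as.numeric(run_py_oracle(script, list(A = A, y = y)))
}
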