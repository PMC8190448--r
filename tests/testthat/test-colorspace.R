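test_that("aggregate_profile averages organs over photos and renormalizes", {
  # a single photo is returned as-is
  rows1 <- data.frame(species = "sp1", photo_id = "p1",
                      organ = c("perianth", "pistil"),
                      R = c(0.9, 0.2), G = c(0.1, 0.2), B = c(0.1, 0.9),
                      proportion = c(0.7, 0.3))
  pr <- aggregate_profile(rows1)
  e <- profile_entry(pr, "sp1")
  expect_equal(e$weights, c(0.7, 0.3))
  expect_equal(unname(e$points[1, ]), c(0.9, 0.1, 0.1))

  # colour centroid across two photos
  rows2 <- data.frame(species = "sp1", photo_id = c("p1", "p2"),
                      organ = "perianth",
                      R = c(0, 1), G = c(0, 1), B = c(0, 1),
                      proportion = 1)
  e2 <- profile_entry(aggregate_profile(rows2), "sp1")
  expect_equal(unname(e2$points[1, ]), c(0.5, 0.5, 0.5))

  # organ weights 0.6/0.4 and 0.5/0.5 -> 0.55/0.45
  rows3 <- data.frame(species = "sp1",
                      photo_id = rep(c("p1", "p2"), each = 2),
                      organ = rep(c("perianth", "pistil"), 2),
                      R = 0.5, G = 0.5, B = 0.5,
                      proportion = c(0.6, 0.4, 0.5, 0.5))
  e3 <- profile_entry(aggregate_profile(rows3), "sp1")
  expect_equal(sort(e3$weights, decreasing = TRUE), c(0.55, 0.45))

  # per-photo proportions far from 1 are an error
  rows_bad <- rows1
  rows_bad$proportion <- c(0.7, 0.5)
  expect_error(aggregate_profile(rows_bad), "sum to 1")
  expect_error(aggregate_profile(rows1[0, ]), "no colour rows")
})

test_that("emd matches hand values and the enumeration LP oracle", {
  p1 <- list(points = matrix(c(0, 0, 0), 1), weights = 1)
  p2 <- list(points = matrix(c(1, 0, 0), 1), weights = 1)
  expect_equal(emd(p1, p1), 0)
  expect_equal(emd(p1, p2), 1)

  # split mass: {(0,0,0):.5,(1,0,0):.5} vs {(1,0,0):1} -> move half, cost 0.5
  p3 <- list(points = rbind(c(0, 0, 0), c(1, 0, 0)), weights = c(0.5, 0.5))
  expect_equal(emd(p3, p2), 0.5)

  expect_error(emd(list(points = p3$points, weights = c(0.5, 0.4)), p2),
               "sum to 1")

  # random profiles against the basic-solution enumeration oracle
  set.seed(21)
  for (i in 1:20) {
    a <- rand_profile(sample(2:4, 1))
    b <- rand_profile(sample(2:4, 1))
    C <- as.matrix(stats::dist(rbind(a$points, b$points)))
    C <- C[seq_len(nrow(a$points)), nrow(a$points) + seq_len(nrow(b$points)),
           drop = FALSE]
    expect_equal(emd(a, b), enum_transport_cost(a$weights, b$weights, C),
                 tolerance = 1e-9)
  }
})

test_that("emd behaves as a metric and ignores mass splitting", {
  set.seed(31)
  profs <- replicate(6, rand_profile(sample(2:5, 1)), simplify = FALSE)
  for (p in profs) expect_equal(emd(p, p), 0, tolerance = 1e-12)
  for (i in 1:5) {
    a <- profs[[i]]; b <- profs[[i + 1]]
    expect_equal(emd(a, b), emd(b, a), tolerance = 1e-10)
  }
  # triangle inequality on all triples
  combs <- utils::combn(6, 3)
  dmat <- matrix(0, 6, 6)
  for (i in 1:5) for (j in (i + 1):6) {
    dmat[i, j] <- dmat[j, i] <- emd(profs[[i]], profs[[j]])
  }
  for (ci in seq_len(ncol(combs))) {
    tri <- combs[, ci]
    expect_lte(dmat[tri[1], tri[2]],
               dmat[tri[1], tri[3]] + dmat[tri[3], tri[2]] + 1e-9)
  }
  # splitting one mass point into two coincident points changes nothing
  a <- profs[[1]]; b <- profs[[2]]
  a_split <- list(points = rbind(a$points, a$points[1, ]),
                  weights = c(a$weights[1] / 2, a$weights[-1], a$weights[1] / 2))
  expect_equal(emd(a_split, b), emd(a, b), tolerance = 1e-9)
})

test_that("distance matrix reduces to Euclidean for single-point profiles", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  prof <- color_profile(data.frame(species = c("s1", "s2", "s3"),
                                   organ = "perianth",
                                   R = pts[, 1], G = pts[, 2], B = pts[, 3],
                                   weight = 1))
  D <- color_distance_matrix(prof)
  expect_equal(sort(D[upper.tri(D)]), c(1, 1, sqrt(2)))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))

  # two identical species -> zero matrix
  prof2 <- color_profile(data.frame(species = c("a", "b"), organ = "perianth",
                                    R = 0.5, G = 0.5, B = 0.5, weight = 1))
  expect_equal(unname(color_distance_matrix(prof2)),
               matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("pca_first_pc fixes the sign and reports variance explained", {
  x <- cbind(R = c(0.1, 0.5, 0.9, 0.3), G = 0.5, B = 0.2)
  rownames(x) <- paste0("s", 1:4)
  pc <- pca_first_pc(x)
  expect_equal(pc$varexp, 1)
  expect_gte(pc$loadings[1], 0)
  # scores ordered like the red channel under the sign convention
  expect_equal(order(pc$scores), order(x[, 1]))

  expect_error(pca_first_pc(x[1:2, ]), "three species")
  expect_error(pca_first_pc(matrix(0.5, 5, 3)), "zero colour variance")

  # isotropic Gaussian: PC1 explains about a third
  set.seed(5)
  iso <- matrix(rnorm(3000), ncol = 3)
  expect_equal(pca_first_pc(iso)$varexp, 1 / 3, tolerance = 0.05)
})

test_that("pcoa embedding reconstructs Euclidean configurations", {
  # four points on a line: first axis recovers the spacings up to sign
  x <- c(0, 1, 3, 6)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  em <- pcoa_embed(D, k = 3)
  expect_equal(as.matrix(dist(em$coords[, 1])), unname(D), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(em$varexp) <= 1e-12))

  # general Euclidean input reconstructs at k = n - 1
  set.seed(9)
  P <- matrix(rnorm(7 * 3), 7, 3)
  D2 <- as.matrix(dist(P))
  dimnames(D2) <- list(paste0("t", 1:7), paste0("t", 1:7))
  em2 <- pcoa_embed(D2, k = 6)
  expect_equal(as.matrix(dist(em2$coords)), unname(D2), tolerance = 1e-6,
               ignore_attr = TRUE)

  # degenerate all-zero distances give all-zero coordinates
  D0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(max(abs(pcoa_embed(D0, k = 2)$coords)), 0)

  expect_error(pcoa_embed(D, k = 4), "k must satisfy")
})
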