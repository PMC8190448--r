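test_that("hull_volume is exact in low dimensions and matches qhull", {
  # 1-D range, 2-D shoelace, simplex determinant
  expect_equal(hull_volume(matrix(c(0, 10, 5))), 10)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(hull_volume(sq), 1)
  expect_equal(hull_volume(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  # unit cube from its 8 corners (facet enumeration path)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(hull_volume(cube), 1, tolerance = 1e-6)
  # degenerate: coplanar points in 3-D
  flat <- cbind(matrix(runif(10), 5, 2), 0.3)
  expect_equal(hull_volume(flat), 0)
  expect_equal(hull_volume(matrix(0.5, 4, 2)), 0)

  # random clouds in 3-D and 4-D against scipy's qhull
  set.seed(14)
  sets <- c(lapply(1:3, function(i) matrix(rnorm(3 * 15), ncol = 3)),
            lapply(1:3, function(i) matrix(rnorm(4 * 12), ncol = 4)))
  ours <- vapply(sets, hull_volume, numeric(1))
  theirs <- py_hull_volumes(sets)
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("fric is the community share of the pool trait volume", {
  pool1 <- matrix(c(0, 2, 4, 7, 10))
  expect_equal(fric(matrix(c(0, 10, 5)), pool1), 1)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(fric(rbind(c(0, 0), c(1, 0), c(0, 1)), sq), 0.5)
  expect_equal(fric(matrix(0.3, 3, 2), sq), 0)
  expect_error(fric(matrix(c(0, 1), 2, 1), pool1), "more than two")
  expect_error(fric(matrix(c(0, 1, 2)), matrix(5, 4, 1)), "zero trait-space")
})

test_that("community_trait_points picks embedding rows or raw pistil lengths", {
  tt <- trait_table(c("A", "B", "C"), c(10, 20, 30), c(4, 4, 4), c(6, 6, 6))
  pts <- community_trait_points(c("A", "C"), "pistil", traits = tt)
  expect_equal(unname(pts[, 1]), c(10, 30))
  expect_error(community_trait_points(c("A", "Z"), "pistil", traits = tt),
               "missing")

  D <- matrix(runif(16), 4, 4); D <- D + t(D); diag(D) <- 0
  dimnames(D) <- list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  em <- suppressWarnings(pcoa_embed(D, k = 3))  # random D need not be Euclidean
  cp <- community_trait_points(c("A", "B", "C"), "color", embedding = em, k = 5)
  # three species span at most 2 axes
  expect_equal(dim(cp), c(3, 2))
  expect_equal(cp, em$coords[c("A", "B", "C"), 1:2])
})

test_that("mpd averages patristic distances over pairs", {
  tr <- tree3()
  expect_equal(mpd(c("A", "B"), tr), 2)
  expect_equal(mpd(c("A", "B", "C"), tr), 10 / 3)
  expect_error(mpd("A", tr), "two species")
})

test_that("independent swap preserves margins and finds the 2x2 checkerboard", {
  m <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  sw <- independent_swap(m, iterations = 1, seed = 1)
  expect_equal(unname(sw), matrix(c(0, 1, 1, 0), 2, 2))

  ones <- matrix(1, 3, 3, dimnames = list(paste0("s", 1:3), paste0("x", 1:3)))
  expect_message(sw2 <- independent_swap(ones, iterations = 10, seed = 1),
                 "unchanged")
  expect_equal(sw2, ones)

  set.seed(3)
  M <- matrix(rbinom(200, 1, 0.3), 20, 10,
              dimnames = list(paste0("s", 1:20), paste0("sp", 1:10)))
  M[rowSums(M) == 0, 1] <- 1
  for (i in 1:5) {
    r <- independent_swap(M, iterations = 500, seed = i)
    expect_equal(rowSums(r), rowSums(M))
    expect_equal(colSums(r), colSums(M))
  }
})

test_that("swap chain reaches every attainable matrix of a 3x3 case", {
  # margins (1,1,1)/(1,1,1): the attainable set is all 6 permutation matrices
  m <- diag(3)
  dimnames(m) <- list(paste0("s", 1:3), paste0("x", 1:3))
  # each successful swap is a transposition, so mix odd and even step counts
  seen <- character(0)
  for (i in 1:200) {
    r <- independent_swap(m, iterations = 6 + i %% 2, seed = i)
    seen <- union(seen, paste(r, collapse = ""))
  }
  expect_equal(length(seen), 6)
})

test_that("dispersal null preserves richness and respects distance decay", {
  set.seed(8)
  m <- matrix(rbinom(40, 1, 0.4), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("sp", 1:5)))
  m[rowSums(m) == 0, 1] <- 1
  m[, colSums(m) == 0][1, ] <- 1
  xy <- data.frame(x = runif(8, 0, 100), y = runif(8, 0, 100),
                   row.names = rownames(m))
  co <- suppressWarnings(community_data(m, xy))
  for (i in 1:5) {
    r <- dispersal_null(co, seed = i)
    expect_equal(rowSums(r), rowSums(co$incidence))
    expect_true(all(r %in% c(0, 1)))
  }

  # all sites at one location: weights collapse to occurrence frequency
  xy0 <- data.frame(x = rep(1, 8), y = rep(1, 8), row.names = rownames(m))
  co0 <- suppressWarnings(community_data(co$incidence, xy0))
  W <- floradiverge:::.dispersal_weights(co0, decay = 0.01)
  fr <- colSums(co0$incidence)
  for (s in 1:8) {
    expect_equal(W[s, ] / sum(W[s, ]),
                 (fr - co0$incidence[s, ]) / sum(fr - co0$incidence[s, ]),
                 tolerance = 1e-12)
  }

  # two-species monotonicity: the nearer species is drawn more often
  m2 <- rbind(f = c(0, 0), a = c(1, 0), b = c(0, 1))
  colnames(m2) <- c("near", "far")
  m2["f", ] <- c(1, 0)  # focal site needs one species
  xy2 <- data.frame(x = c(0, 10, 200), y = 0, row.names = rownames(m2))
  co2 <- community_data(m2, xy2)
  W2 <- floradiverge:::.dispersal_weights(co2, decay = 1 / 50)
  expect_gt(W2["f", "near"], W2["f", "far"])
  set.seed(99)
  draws <- replicate(2000, floradiverge:::.dispersal_draw(co2$incidence, W2)["f", "near"])
  p_near <- W2["f", "near"] / sum(W2["f", ])
  expect_equal(mean(draws), p_near, tolerance = 0.05)
})

test_that("dispersal null conserves species frequencies in expectation", {
  # symmetric toy: equidistant sites, equal frequencies -> exact conservation
  m <- rbind(s1 = c(1, 1, 0, 0), s2 = c(0, 1, 1, 0),
             s3 = c(0, 0, 1, 1), s4 = c(1, 0, 0, 1))
  colnames(m) <- paste0("sp", 1:4)
  xy <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
                   row.names = rownames(m))
  co <- community_data(m, xy)
  set.seed(17)
  W <- floradiverge:::.dispersal_weights(co)
  acc <- numeric(4)
  n_rep <- 10000
  for (i in seq_len(n_rep)) {
    acc <- acc + colSums(floradiverge:::.dispersal_draw(co$incidence, W))
  }
  expect_equal(acc / n_rep, colSums(m), tolerance = 0.05, ignore_attr = TRUE)
})

test_that("null_distribution verdicts follow the empirical quantiles", {
  set.seed(2)
  reps <- rnorm(999)
  nd <- null_distribution(median(reps), reps)
  expect_equal(nd$verdict, "within")
  expect_equal(null_distribution(10, reps)$verdict, "above")
  expect_equal(null_distribution(-10, reps)$verdict, "below")
  expect_equal(nd$n_null, 999)
  expect_true(nd$lower_q <= nd$observed && nd$observed <= nd$upper_q)
})

test_that("assembly metrics agree with hand computation on a tiny world", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  tt <- trait_table(c("A", "B", "C", "D"), c(10, 20, 30, 40),
                    c(4, 4, 4, 4), c(6, 6, 6, 6))
  m <- rbind(s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1), s3 = c(1, 0, 0, 1))
  colnames(m) <- c("A", "B", "C", "D")
  xy <- data.frame(x = c(0, 5, 9), y = 0, row.names = rownames(m))
  co <- community_data(m, xy)
  D <- matrix(runif(16, 0.2, 1), 4, 4); D <- D + t(D); diag(D) <- 0
  dimnames(D) <- list(colnames(m), colnames(m))
  em <- pcoa_embed(D, k = 3)
  res <- assembly_metrics(co, tree = tr, embedding = em, traits = tt)

  # MPD by path sums
  expect_equal(res$per_site$mpd[1], mean(c(2, 4, 4)))          # A,B,C
  expect_equal(res$per_site$mpd[3], 4)                          # A,D
  # pistil FRic: range ratio over sites with > 2 species
  expect_equal(res$per_site$fric_pistil[1], (30 - 10) / 30)
  expect_equal(res$per_site$fric_pistil[2], (40 - 20) / 30)
  expect_true(is.na(res$per_site$fric_pistil[3]))
  # colour FRic: triangle area in the first two PCoA axes over pool area
  tri <- function(P) abs(det(rbind(P[2, ] - P[1, ], P[3, ] - P[1, ]))) / 2
  pool_area <- hull_volume(em$coords[, 1:2])
  expect_equal(res$per_site$fric_color[1],
               tri(em$coords[c("A", "B", "C"), 1:2]) / pool_area)
  expect_equal(res$regional_mean[["mpd"]], mean(res$per_site$mpd))
})

test_that("assembly_test flags a divergence-filtered world and centres a median", {
  # observed placed at its own null median -> 'within'
  set.seed(6)
  reps <- rnorm(199)
  expect_equal(null_distribution(stats::median(reps), reps)$verdict, "within")

  cfg <- synth_config(n_species = 15, n_sites = 50, seed = 42)
  tr <- sim_tree(cfg)
  tt <- sim_phenology(tr, cfg)
  pist <- stats::setNames(tt$pistil_length, tt$species)
  co <- sim_communities(tr, trait = as.matrix(pist), cfg = cfg,
                        model = "divergence_filter")
  res <- assembly_test(co, traits = tt, metrics = "fric_pistil",
                       n_reps = 199, seed = 1,
                       swap_burnin = 2000, swap_thin = 150)
  expect_equal(res$fric_pistil$verdict, "above")
})
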