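test_that("tree simulation is seeded, sized and ultrametric", {
  cfg <- synth_config(n_species = 52, seed = 77)
  t1 <- sim_tree(cfg)
  t2 <- sim_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 52)
  expect_true(attr(t1, "ultrametric"))

  t3 <- sim_tree(synth_config(n_species = 52, seed = 78))
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
})

test_that("pure-birth trees grow lineages at about the birth rate", {
  # reconstructed pure-birth LTT is log-linear with slope ~ birth rate
  set.seed(50)
  slopes <- vapply(1:40, function(i) {
    cfg <- synth_config(n_species = 40, birth = 0.3, death = 0,
                        seed = 5000 + i)
    l <- ltt(sim_tree(cfg))
    stats::coef(stats::lm(log(l$n_lineages) ~ l$time))[2]
  }, numeric(1))
  expect_equal(unname(mean(slopes)), 0.3, tolerance = 0.2)
})

test_that("trait models realize their generative signatures", {
  set.seed(51)
  # allopatric BM: mean squared standardized contrast estimates sigma2
  s2hat <- vapply(1:60, function(i) {
    tr <- validate_phylogeny(ape::rphylo(40, 0.3, 0.1))
    mean(ape::pic(sim_traits(tr, "allopatric_bm",
                             params = list(sigma2 = 2))$tips, tr)^2)
  }, numeric(1))
  expect_equal(mean(s2hat), 2, tolerance = 0.1)

  # speciational: variance scales with node count, not path length
  Tdepth <- 5
  star <- ape::stree(20, "star"); star$edge.length <- rep(Tdepth, 20)
  cat20 <- ape::stree(20, "left"); cat20$edge.length <- rep(1, nrow(cat20$edge))
  cat20 <- validate_phylogeny(cat20)
  v_star <- vapply(1:40, function(i)
    var(sim_traits(validate_phylogeny(star), "speciational",
                   params = list(tau2 = 1, sigma2_bm = 1e-4))$tips), numeric(1))
  v_cat <- vapply(1:40, function(i)
    var(sim_traits(cat20, "speciational",
                   params = list(tau2 = 1, sigma2_bm = 1e-4))$tips), numeric(1))
  expect_gt(mean(v_cat), 2 * mean(v_star))

  # negative interactions: realized edge rates rise toward the present
  rho <- vapply(1:20, function(i) {
    tr <- validate_phylogeny(ape::rphylo(40, 0.3, 0.1))
    st <- sim_traits(tr, "negative_interactions", params = list(gamma = 0.2))
    child_depth <- floradiverge:::.node_depths(tr)[tr$edge[, 2]]
    cor(st$edge_rates, child_depth, method = "spearman")
  }, numeric(1))
  expect_gte(mean(rho > 0), 0.95)

  expect_error(sim_traits(tree3(), "no_such_model"), "arg")
})

test_that("community generator hits the configured richness profile", {
  cfg <- synth_config(n_species = 30, n_sites = 1000, seed = 52)
  tr <- sim_tree(cfg)
  co <- sim_communities(tr, cfg = cfg, model = "random")
  rich <- rowSums(co$incidence)
  obs <- tabulate(rich, nbins = 5)
  p <- cfg$richness_probs
  chi <- stats::chisq.test(obs, p = p)
  expect_gt(chi$p.value, 0.01)
  expect_equal(mean(rich), sum(p * (1:5)), tolerance = 0.1)
})

test_that("phenology generator spans the uniform and synchronous limits", {
  cfg_hi <- synth_config(n_species = 60, kappa = 500, seed = 53)
  tr <- sim_tree(cfg_hi)
  tt_hi <- sim_phenology(tr, cfg_hi)
  expect_gt(rayleigh_test(flowering_angles(tt_hi))$statistic, 0.95)
  # September-centred peak
  mid_month <- round(12 * months_to_angle(9, 9) / (2 * pi)) + 1
  expect_equal(mid_month, 9)

  cfg_lo <- synth_config(n_species = 300, kappa = 0, seed = 54)
  tr_lo <- sim_tree(cfg_lo)
  tt_lo <- sim_phenology(tr_lo, cfg_lo)
  expect_lt(rayleigh_test(flowering_angles(tt_lo))$statistic, 0.15)
  expect_true(all(tt_lo$pistil_length > 0))
})

test_that("colour profiles are valid weighted point sets", {
  cfg <- synth_config(n_species = 25, seed = 55)
  tr <- sim_tree(cfg)
  pf <- sim_color_profiles(tr, cfg)
  sums <- tapply(pf$weight, pf$species, sum)
  expect_equal(as.numeric(sums), rep(1, 25), tolerance = 1e-9)
  expect_true(all(pf[, c("R", "G", "B")] >= 0 & pf[, c("R", "G", "B")] <= 1))
  counts <- table(pf$species)
  expect_true(all(counts >= 3 & counts <= 6))
})

test_that("worlds are reproducible and write/read cleanly", {
  cfg <- synth_config(n_species = 15, n_sites = 40, seed = 56)
  w1 <- sim_world(cfg)
  w2 <- sim_world(cfg)
  expect_identical(w1$community$incidence, w2$community$incidence)
  expect_identical(w1$traits$pistil_length, w2$traits$pistil_length)
  expect_identical(ape::write.tree(w1$tree), ape::write.tree(w2$tree))

  dir <- withr::local_tempdir()
  write_world(w1, dir)
  tr <- read_phylogeny(file.path(dir, "tree.nwk"))
  co <- read_community(file.path(dir, "incidence.csv"),
                       file.path(dir, "coordinates.csv"))
  tt <- read_traits(file.path(dir, "traits.csv"))
  pf <- aggregate_profile(read_color_rows(file.path(dir, "color_rows.csv")))
  expect_equal(sort(tr$tip.label), sort(w1$tree$tip.label))
  expect_equal(co$incidence, w1$community$incidence)
  expect_equal(tt$pistil_length, w1$traits$pistil_length, tolerance = 1e-9)
  expect_equal(nrow(pf), nrow(w1$profile))
})

test_that("the three trait models separate along the predicted diagnostics", {
  # paired design: all three models are simulated on the same tree, so the
  # diagnostics compare like with like and estimator artefacts cancel
  set.seed(57)
  n_rep <- 16
  k_spec <- k_allo <- dtt_ok <- b_neg <- b_allo <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- synth_config(n_species = 50, seed = 6000 + i)
    tr <- sim_tree(cfg)
    dv <- div_rate_proxy(tr)
    x_spec <- sim_traits(tr, "speciational",
                         params = list(tau2 = 1, sigma2_bm = 0.01))$tips
    x_allo <- sim_traits(tr, "allopatric_bm")$tips
    x_neg <- sim_traits(tr, "negative_interactions",
                        params = list(gamma = 0.5))$tips
    k_spec[i] <- blomberg_k(tr, x_spec, n_perm = 0)$K
    k_allo[i] <- blomberg_k(tr, x_allo, n_perm = 0)$K
    prof <- dtt(tr, x_allo, n_sims = 99, seed = i)
    dtt_ok[i] <- mean(prof$disparity >= prof$lower & prof$disparity <= prof$upper)
    beta_for <- function(x) {
      rr <- ridge_rates(tr, x)
      cf <- rate_regression(branch_rate_table(tr, rr$rate, dv),
                            "age", tr)$coefficients
      cf$estimate[cf$term == "age"]
    }
    b_neg[i] <- beta_for(x_neg)
    b_allo[i] <- beta_for(x_allo)
  }
  # speciational trait change tracks node counts: K sits below the BM traits
  expect_gt(mean(k_spec < k_allo), 0.5)
  # allopatric BM stays inside its own DTT envelope
  expect_gt(mean(dtt_ok >= 0.9), 0.5)
  # diversity-dependent rates rise toward the present: the rate-age slope
  # exceeds its value for time-homogeneous drift on the same tree
  expect_gt(mean(b_neg > b_allo), 0.5)
})
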