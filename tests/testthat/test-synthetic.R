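test_that("pure-birth trees are ultrametric with the requested height", {
  cherry <- simulate_tree(2, 30, seed = 81)
  expect_equal(unname(tip_depths(cherry)), c(30, 30))
  set.seed(82)
  for (r in 1:8) {
    tr <- simulate_tree(sample(3:40, 1), 30)
    expect_true(is_ultrametric(tr, tol = 1e-8))
    expect_equal(tree_height(tr), 30, tolerance = 1e-10)
  }
})

test_that("unscaled tree heights match the Yule waiting-time expectation", {
  # from k lineages the next split waits Exp(k); expected height for n tips
  # is sum_{k=2}^{n-1} 1/k plus the final Exp(n) extension
  set.seed(83)
  n <- 6
  expected <- sum(1 / (2:(n - 1))) + 1 / n
  hs <- replicate(400, tree_height(simulate_tree(n, height = NULL)))
  expect_lt(abs(mean(hs) - expected), 4 * sd(hs) / sqrt(length(hs)))
})

test_that("regime histories are consistent, stationary, and reproducible", {
  set.seed(84)
  tr <- simulate_tree(25, 30)
  h0 <- simulate_regime_history(tr, 0, 0, seed = 1)
  expect_equal(length(unique(unclass(h0$states))), 1L)

  h1 <- simulate_regime_history(tr, 0.03, 0.91, seed = 2)
  h2 <- simulate_regime_history(tr, 0.03, 0.91, seed = 2)
  expect_identical(h1$map$edge_maps, h2$map$edge_maps)

  # tip state matches the end of the mapped history on its terminal branch
  for (i in seq_len(5)) {
    k <- which(tr$edge[, 2] == i)
    e <- h1$map$edge_maps[[k]]
    expect_equal(unname(e[nrow(e), 2]),
                 match(unclass(h1$states)[[tr$tip.label[i]]], c("low", "high")))
  }

  # marginal tip-state frequency equals the stationary low fraction
  frac <- mean(replicate(300, {
    t2 <- simulate_tree(20, 30)
    mean(unclass(simulate_regime_history(t2, 0.03, 0.91)$states) == "low")
  }))
  expect_lt(abs(frac - 0.91 / 0.94), 0.025)
})

test_that("study histories represent both regimes", {
  set.seed(85)
  tr <- simulate_tree(60, 30)
  h <- simulate_study_history(tr, 0.05, 0.05, min_minority_frac = 0.2)
  expect_gte(min(table(unclass(h$states))) / 60, 0.2)
})

test_that("the design generator emits the full factorial of individuals", {
  ex <- simulate_experiment(synth_config(n_taxa = 10, seed = 7))
  expect_equal(nrow(ex$individuals), 10 * 2 * 3 * 3)
  expect_true(all(ex$individuals$resistance > 0 & ex$individuals$resistance < 1))
  expect_true(all(ex$growth$leaf_length_mm >= 0))
  expect_equal(length(unique(ex$individuals$block)), 6L)
  # determinism under the config seed
  ex2 <- simulate_experiment(synth_config(n_taxa = 10, seed = 7))
  expect_identical(ex$individuals, ex2$individuals)
})

test_that("noiseless designs reproduce species growth curves exactly", {
  cfg <- synth_config(n_taxa = 5, sd_line_asym = 0, sd_line_xmid = 0,
                      sd_round_asym = 0, sd_resid = 0, seed = 11)
  ex <- simulate_experiment(cfg)
  g1 <- ex$growth[ex$growth$plant == ex$individuals$plant[1], ]
  i1 <- ex$individuals[1, ]
  expect_equal(g1$leaf_length_mm,
               i1$ASYM_true / (1 + exp((i1$XMID_true - g1$day) / i1$scal_true)),
               tolerance = 1e-12)
  f <- fit_logistic(g1$day, g1$leaf_length_mm)
  expect_equal(c(f$ASYM, f$XMID, f$scal),
               c(i1$ASYM_true, i1$XMID_true, i1$scal_true), tolerance = 1e-6)
})

test_that("the full pipeline recovers the heat optimum separation sign", {
  # simulate -> per-plant logistic fits -> species means -> OUM fit
  set.seed(86)
  hits <- 0L; R <- 6
  for (r in 1:R) {
    cfg <- synth_config(n_taxa = 30, seed = 1000 + r, q_lh = 0.05, q_hl = 0.05)
    ex <- simulate_experiment(cfg)
    heat <- ex$growth[ex$growth$treatment == "Heat", ]
    fits <- do.call(rbind, lapply(split(heat, heat$plant), function(g) {
      fl <- fit_logistic(g$day, g$leaf_length_mm)
      if (!fl$converged) return(NULL)
      data.frame(species = g$species[1], treatment = "Heat",
                 round = g$round[1], plant = g$plant[1], value = fl$ASYM)
    }))
    agg <- aggregate_species_means(fits)
    dat <- data.frame(species = agg$species, mean = agg$mean, se = agg$se)
    f <- fit_evo_model("OUM", ex$tree, dat, map = ex$map)
    if (isTRUE(f$converged) &&
        f$params$theta_low > f$params$theta_high) hits <- hits + 1L
  }
  expect_gte(hits, R - 1L)
})

test_that("validation study produces sane error-rate structure", {
  set.seed(87)
  tr <- simulate_tree(40, 30)
  h <- simulate_study_history(tr, 0.05, 0.05, min_minority_frac = 0.2)
  rep_ <- run_validation_study(tr, h$map, se_levels = c(0, 8),
                               dtheta_levels = c(0, 30),
                               gen_models = c("OUM", "BM1"),
                               replicates = 8, seed = 3)
  expect_s3_class(rep_, "validation_report")
  expect_true(all(rowSums(rep_[, c("WN", "BM1", "BMM", "OU1", "OUM")]) == 8))
  # separated optima are detected far more often than coincident ones
  null_rate <- rep_$OUM[rep_$model == "OUM" & rep_$dtheta == 0 &
                          rep_$se == 0] / 8
  det_rate <- rep_$OUM[rep_$model == "OUM" & rep_$dtheta == 30 &
                         rep_$se == 0] / 8
  expect_gte(det_rate, null_rate + 0.5)
  # measurement error cannot make detection easier
  fn0 <- rep_$fn[rep_$model == "OUM" & rep_$dtheta == 30 & rep_$se == 0]
  fn8 <- rep_$fn[rep_$model == "OUM" & rep_$dtheta == 30 & rep_$se == 8]
  expect_gte(fn8, fn0)
})

test_that("consensus stability under species removal behaves at the limits", {
  set.seed(88)
  tr <- simulate_tree(40, 30)
  h <- simulate_study_history(tr, 0.05, 0.05, min_minority_frac = 0.2)
  p <- evo_params("OUM", alpha = 0.2, sigma2 = 4, theta_low = 70,
                  theta_high = 24)
  dat <- simulate_traits(tr, p, h$map, se = 1)
  same <- run_bootstrap_robustness(tr, dat, h$map, remove_fraction = 0,
                                   replicates = 1, seed = 1)
  expect_equal(same$agreement, 1)
  strong <- run_bootstrap_robustness(tr, dat, h$map, replicates = 6, seed = 2)
  expect_equal(strong$full_consensus, "OUM")
  expect_gte(strong$agreement, 0.8)

  wn <- simulate_traits(tr, evo_params("WN", mu = 0, sigma2 = 1), seed = 3)
  null <- run_bootstrap_robustness(tr, wn, h$map, replicates = 6, seed = 4)
  # pure noise: the adaptive model is never the modal consensus
  modal <- names(sort(table(null$winners), decreasing = TRUE))[1]
  expect_false(modal == "OUM")
})
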