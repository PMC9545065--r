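fake_fit <- function(model, aicc, k = c(WN = 2, BM1 = 2, BMM = 3, OU1 = 3,
                                        OUM = 4)[[model]],
                     alpha = 0.2, converged = TRUE) {
  structure(list(model = model,
                 params = if (model %in% c("OU1", "OUM"))
                   list(model = model, alpha = alpha, theta_low = 1,
                        theta_high = 2) else list(model = model),
                 logLik = -aicc / 2, k = k, AICc = aicc, n = 50,
                 converged = converged), class = "evo_fit")
}
fake_map_fits <- function(aiccs) {
  stats::setNames(Map(fake_fit, names(aiccs), aiccs), names(aiccs))
}

test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(-50, 2, 100), 104 + 12 / 97)
  expect_equal(aicc(-50, 0, 10), 100)
  expect_lt(abs(aicc(-10, 4, 1e5) - (20 + 8)), 1e-3)   # tends to AIC
  expect_error(aicc(-50, 5, 6), "n > k")
})

test_that("consensus across maps reports winner, support and minority", {
  one_map <- fake_map_fits(c(WN = 110, BM1 = 108, BMM = 109, OU1 = 106,
                             OUM = 103.64))
  cons <- consensus_best(rep(list(one_map), 5))
  expect_equal(cons$consensus, "OUM")
  expect_equal(cons$delta_aicc, -2.36)
  expect_equal(cons$support_class, "clear")

  # exact tie resolves to the model with fewer parameters, support among-best
  tied <- fake_map_fits(c(WN = 110, BM1 = 105, BMM = 109, OU1 = 108,
                          OUM = 105))
  cons <- consensus_best(list(tied))
  expect_equal(cons$consensus, "BM1")
  expect_equal(cons$support_class, "among-best")

  # 60/40 split across maps: majority wins, minority on record
  m_oum <- fake_map_fits(c(WN = 110, BM1 = 108, BMM = 109, OU1 = 109,
                           OUM = 104))
  m_ou1 <- fake_map_fits(c(WN = 110, BM1 = 108, BMM = 109, OU1 = 104,
                           OUM = 109))
  cons <- consensus_best(c(rep(list(m_oum), 6), rep(list(m_ou1), 4)))
  expect_equal(cons$consensus, "OUM")
  expect_equal(unname(cons$votes[["OU1"]]), 4L)

  # permutation invariance in map order
  cons2 <- consensus_best(c(rep(list(m_ou1), 4), rep(list(m_oum), 6)))
  expect_equal(cons2$consensus, cons$consensus)
  expect_equal(cons2$delta_aicc, cons$delta_aicc)

  # failed fits are excluded per map
  failed <- fake_map_fits(c(WN = 110, BM1 = 108, BMM = 109, OU1 = 106,
                            OUM = 104))
  failed$OUM$converged <- FALSE
  expect_equal(consensus_best(list(failed))$consensus, "OU1")
  expect_error(consensus_best(list(lapply(failed, function(f) {
    f$converged <- FALSE; f }))), "failed")
})

test_that("phylogenetic half-life is ln(2)/alpha", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.04475), log(2) / 0.04475, tolerance = 1e-12)
  expect_equal(half_life(0.04475), 15.49, tolerance = 1e-3)
  expect_lt(half_life(1e6), 1e-5)
  expect_error(half_life(0), "alpha")
})

test_that("the (mean - 1.64 SD) > 0 significance rule is exact", {
  s <- halflife_significance(rep(5, 10))
  expect_equal(s$sd, 0)
  expect_true(s$significant)
  s <- halflife_significance(c(1, 100))
  expect_equal(s$mean, 50.5)
  expect_equal(s$sd, sd(c(1, 100)))
  expect_false(s$significant)
})

test_that("bootstrap half-life recovers the generating time scale", {
  set.seed(43)
  tr <- simulate_tree(100, 30)
  p <- evo_params("OU1", alpha = 0.2, sigma2 = 4, theta = 50)
  dat <- simulate_traits(tr, p, se = 0.5)
  bb <- bootstrap_half_life(tr, dat, model = "OU1", n_boot = 40, seed = 6)
  expect_lt(abs(bb$mean - half_life(0.2)) / half_life(0.2), 0.5)
  expect_true(bb$significant)
  expect_error(bootstrap_half_life(tr, dat, model = "OU1", n_boot = 1),
               "at least 2")
})

test_that("treatment contrasts on half-lives are exact on constructed data", {
  traits <- paste0("tr", 1:6)
  mild <- c(2, 4, 8, 16, 5, 10)
  tab <- rbind(
    data.frame(trait = traits, treatment = "Mild", t_half = mild),
    data.frame(trait = traits, treatment = "Frost", t_half = mild / 2))
  ct <- treatment_halflife_contrast(tab, n_boot = 50, seed = 1)
  expect_equal(unname(ct$contrasts[["Frost"]]), log(0.5), tolerance = 1e-6)
  expect_equal(unname(ct$percent_change[["Frost"]]), -50, tolerance = 1e-4)

  tab2 <- tab; tab2$t_half <- rep(mild, 2)
  ct2 <- treatment_halflife_contrast(tab2, n_boot = 50, seed = 1)
  expect_lt(abs(ct2$contrasts[["Frost"]]), 1e-8)

  expect_error(treatment_halflife_contrast(tab[tab$treatment == "Mild", ]),
               "2 treatments")
})

test_that("half-life contrast intervals cover a simulated effect", {
  set.seed(42)
  covered <- replicate(20, {
    ntr <- 10
    d <- expand.grid(trait = paste0("t", seq_len(ntr)),
                     treatment = c("Mild", "Frost"),
                     stringsAsFactors = FALSE)
    re <- rep(rnorm(ntr, 0, 0.5), 2)
    d$t_half <- exp(1.5 + re + ifelse(d$treatment == "Frost", -0.6, 0) +
                      rnorm(nrow(d), 0, 0.1))
    ct <- treatment_halflife_contrast(d, n_boot = 100)
    ct$ci["Frost", 1] <= -0.6 && ct$ci["Frost", 2] >= -0.6
  })
  expect_gte(mean(covered), 0.8)
})
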