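make_mapped_tree <- function(n = 6, seed = 31, q_lh = 0.2, q_hl = 0.3) {
  tr <- simulate_tree(n, 10, seed = seed)
  h <- simulate_regime_history(tr, q_lh, q_hl, seed = seed + 1)
  list(tree = tr, map = h$map, states = h$states)
}

test_that("OUM expectation collapses, saturates, and matches quadrature", {
  mt <- make_mapped_tree()
  p_eq <- evo_params("OUM", alpha = 0.3, sigma2 = 1, theta_low = 7,
                     theta_high = 7)
  expect_equal(unname(model_mean(mt$tree, p_eq, mt$map)), rep(7, 6))

  # strong pull: each tip sits at the optimum of its terminal regime segment
  p_str <- evo_params("OUM", alpha = 1000, sigma2 = 1,
                      theta_low = 70.16, theta_high = 23.65)
  mu <- model_mean(mt$tree, p_str, mt$map)
  want <- c(70.16, 23.65)[mt$map$tip_states[mt$tree$tip.label]]
  expect_equal(unname(mu), unname(want), tolerance = 1e-6)

  # quadrature oracle at moderate pull
  al <- 0.1; th <- c(5, -3)
  p <- evo_params("OUM", alpha = al, sigma2 = 1, theta_low = th[1],
                  theta_high = th[2])
  segs <- map_tip_segments(mt$tree, mt$map)
  Tt <- tree_height(mt$tree)
  mq <- vapply(segs, function(s) {
    f <- function(t) {
      st <- s[findInterval(t, s[, "start"], rightmost.closed = TRUE), "state"]
      th[st] * al * exp(-al * (Tt - t))
    }
    stats::integrate(Vectorize(f), 0, Tt, subdivisions = 2000L,
                     rel.tol = 1e-10)$value + th[s[1, "state"]] * exp(-al * Tt)
  }, 0)
  expect_equal(unname(model_mean(mt$tree, p, mt$map)), unname(mq),
               tolerance = 1e-4)
  expect_error(model_mean(mt$tree, p), "map")
})

test_that("model covariances satisfy their limits and collapses", {
  mt <- make_mapped_tree()
  C <- phylo_covariance(mt$tree)
  # OU at vanishing pull tends to Brownian motion
  p <- evo_params("OU1", alpha = 1e-8, sigma2 = 2, theta = 0)
  V <- model_covariance(mt$tree, p)
  expect_lt(max(abs(V - 2 * C) / max(2 * C)), 1e-4)
  # regime-blind BMM equals BM1 exactly
  pb <- evo_params("BMM", x0 = 0, sigma2_low = 1.7, sigma2_high = 1.7)
  expect_equal(model_covariance(mt$tree, pb, mt$map),
               model_covariance(mt$tree, evo_params("BM1", x0 = 0,
                                                    sigma2 = 1.7)),
               tolerance = 1e-12)
})

test_that("OUM covariance matches exact-transition path simulation", {
  mt <- make_mapped_tree(n = 4, seed = 33)
  al <- 0.25; s2 <- 2; th <- c(3, -3)
  p <- evo_params("OUM", alpha = al, sigma2 = s2, theta_low = th[1],
                  theta_high = th[2])
  set.seed(34)
  X <- simulate_ou_paths(mt$tree, mt$map, al, s2, th, 50000)
  V <- model_covariance(mt$tree, p, mt$map)[colnames(X), colnames(X)]
  mu <- model_mean(mt$tree, p, mt$map)[colnames(X)]
  # Monte-Carlo tolerance ~ 4 standard errors of a covariance entry
  tol <- 4 * max(diag(V)) / sqrt(50000 / 2)
  expect_lt(max(abs(cov(X) - V)), tol)
  expect_lt(max(abs(colMeans(X) - mu)), tol)
})

test_that("model likelihood equals independent dense MVN computations", {
  mt <- make_mapped_tree()
  set.seed(35)
  se <- runif(6, 0.1, 0.5)
  dat <- data.frame(species = mt$tree$tip.label, mean = rnorm(6, 2, 3),
                    se = se)
  params <- list(
    evo_params("WN", mu = 1, sigma2 = 2),
    evo_params("BM1", x0 = 1, sigma2 = 0.5),
    evo_params("BMM", x0 = 1, sigma2_low = 0.5, sigma2_high = 2),
    evo_params("OU1", alpha = 0.3, sigma2 = 1, theta = 2),
    evo_params("OUM", alpha = 0.3, sigma2 = 1, theta_low = 2,
               theta_high = -1))
  for (p in params) {
    V <- model_covariance(mt$tree, p, mt$map, se = setNames(se, dat$species))
    mu <- model_mean(mt$tree, p, mt$map)
    y <- setNames(dat$mean, dat$species)[mt$tree$tip.label]
    expect_equal(model_loglik(mt$tree, p, dat, mt$map),
                 dense_mvn_loglik(y, mu, V), tolerance = 1e-10)
  }
  # diagonal case: WN with SE = 0 is a sum of independent normal densities
  dat0 <- dat; dat0$se <- 0
  p <- evo_params("WN", mu = 1, sigma2 = 2)
  expect_equal(model_loglik(mt$tree, p, dat0),
               sum(dnorm(dat0$mean, 1, sqrt(2), log = TRUE)))
  # adding a zero SE vector changes nothing
  expect_equal(model_loglik(mt$tree, p, dat0),
               model_loglik(mt$tree, p, dat0[, c("species", "mean")]))
})

test_that("likelihoods nest across models and respect time rescaling", {
  mt <- make_mapped_tree(n = 12, seed = 36)
  p <- evo_params("OUM", alpha = 0.3, sigma2 = 2, theta_low = 5,
                  theta_high = -2)
  dat <- simulate_traits(mt$tree, p, mt$map, se = 0.3, seed = 37)
  fits <- fit_all_evo_models(mt$tree, dat, mt$map)
  expect_gte(fits$OUM$logLik, fits$OU1$logLik - 1e-4)
  expect_gte(fits$BMM$logLik, fits$BM1$logLik - 1e-4)

  # rescale time by c, (alpha, sigma2) by 1/c: identical OU likelihood
  c_ <- 4
  tr2 <- mt$tree; tr2$edge.length <- tr2$edge.length * c_
  map2 <- mt$map
  map2$edge_maps <- lapply(map2$edge_maps, function(e) {
    e[, 1] <- e[, 1] * c_; e })
  p1 <- evo_params("OU1", alpha = 0.3, sigma2 = 2, theta = 1)
  p2 <- evo_params("OU1", alpha = 0.3 / c_, sigma2 = 2 / c_, theta = 1)
  expect_equal(model_loglik(mt$tree, p1, dat),
               model_loglik(tr2, p2, dat), tolerance = 1e-8)
})

test_that("ML fitting recovers generating parameters and flags degeneracy", {
  set.seed(38)
  tr <- simulate_tree(60, 30)
  p <- evo_params("BM1", x0 = 0, sigma2 = 1)
  hits <- 0L
  for (r in 1:10) {
    dat <- simulate_traits(tr, p)
    f <- fit_evo_model("BM1", tr, dat)
    if (f$params$sigma2 > 0.7 && f$params$sigma2 < 1.3) hits <- hits + 1L
  }
  expect_gte(hits, 7L)

  const <- data.frame(species = tr$tip.label, mean = 5, se = 0)
  f <- fit_evo_model("OU1", tr, const)
  expect_false(f$converged)
})

test_that("trait simulation is deterministic and matches model moments", {
  mt <- make_mapped_tree(n = 5, seed = 39)
  p <- evo_params("OUM", alpha = 0.4, sigma2 = 1.5, theta_low = 2,
                  theta_high = -2)
  a <- simulate_traits(mt$tree, p, mt$map, se = 0.2, seed = 99)
  b <- simulate_traits(mt$tree, p, mt$map, se = 0.2, seed = 99)
  expect_identical(a, b)

  # vanishing noise returns the expectation exactly
  p0 <- evo_params("OUM", alpha = 0.4, sigma2 = 1e-12, theta_low = 2,
                   theta_high = -2)
  d0 <- simulate_traits(mt$tree, p0, mt$map, se = 0)
  expect_equal(d0$mean, unname(model_mean(mt$tree, p0, mt$map)),
               tolerance = 1e-5)

  set.seed(40)
  Y <- t(replicate(10000, simulate_traits(mt$tree, p, mt$map)$mean))
  V <- model_covariance(mt$tree, p, mt$map)
  mu <- model_mean(mt$tree, p, mt$map)
  tol <- 4 * max(diag(V)) / sqrt(10000 / 2)
  expect_lt(max(abs(cov(Y) - V)), tol)
  expect_lt(max(abs(colMeans(Y) - mu)), tol)
})
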