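test_that("regime assignment applies the 1500 m closed-low convention", {
  el <- c(sp1 = 400, sp2 = 2800, sp3 = 1500, sp4 = 1501)
  r <- assign_regimes(el)
  expect_equal(unclass(r)[["sp1"]], "low")    # foothill species
  expect_equal(unclass(r)[["sp2"]], "high")   # alpine species
  expect_equal(unclass(r)[["sp3"]], "low")    # boundary is low
  expect_equal(unclass(r)[["sp4"]], "high")
  expect_true(all(assign_regimes(c(a = 1600, b = 2000)) == "high"))
  expect_error(assign_regimes(el, species = c("sp1", "spX")), "spX")
})

test_that("Mk likelihood matches analytic boundary cases", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  allsame <- structure(rep("low", 3), names = tr$tip.label, class = "regimes")
  expect_equal(mk_loglik(tr, allsame, 0, 0), log(0.5))
  mixed <- structure(c("low", "high", "low"), names = tr$tip.label,
                     class = "regimes")
  expect_equal(mk_loglik(tr, mixed, 0, 0), -Inf)
  expect_error(mk_loglik(tr, mixed, -0.1, 0.2), "non-negative")
})

test_that("Mk likelihood equals the enumeration oracle on small trees", {
  set.seed(21)
  for (r in 1:20) {
    tr <- simulate_tree(sample(4:6, 1), 8)
    st <- rand_regimes(tr)
    a <- runif(1, 0, 1.2); b <- runif(1, 0, 1.2)
    expect_equal(mk_loglik(tr, st, a, b), enum_mk_loglik(tr, st, a, b),
                 tolerance = 1e-12)
  }
})

test_that("Mk likelihood is invariant to tip ordering", {
  set.seed(22)
  tr <- simulate_tree(8, 10)
  st <- rand_regimes(tr)
  ll <- mk_loglik(tr, st, 0.2, 0.5)
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(mk_loglik(tr2, st, 0.2, 0.5), ll, tolerance = 1e-10)
})

test_that("ML rates hit the boundary for monomorphic tips", {
  set.seed(23)
  tr <- simulate_tree(12, 10)
  st <- structure(rep("low", 12), names = tr$tip.label, class = "regimes")
  fe <- fit_mk(tr, st, "ER")
  expect_lt(fe$rates[["q_low_high"]], 1e-4)
  expect_equal(fe$logLik, log(0.5), tolerance = 1e-3)
  # ARD can absorb the root-prior mass by an instant high->low collapse,
  # but the observed rate still sits at the lower bound
  fa <- fit_mk(tr, st, "ARD")
  expect_lt(fa$rates[["q_low_high"]], 1e-4)
  expect_gte(fa$logLik, fe$logLik)
})

test_that("asymmetric switching rates are recovered within sampling error", {
  # strongly asymmetric generating rates per mya; tip data carry limited
  # information about the rate out of the short-lived high regime, so the
  # check targets the asymmetry direction and order-of-magnitude accuracy
  set.seed(24)
  q_true <- c(0.030, 0.910)
  fits <- list()
  while (length(fits) < 6L) {
    tr <- simulate_tree(150, 30)
    h <- simulate_regime_history(tr, q_true[1], q_true[2])
    if (min(table(factor(unclass(h$states),
                         levels = c("low", "high")))) < 5L) next
    fits[[length(fits) + 1L]] <- fit_mk(tr, h$states, "ARD")
  }
  rates <- t(vapply(fits, coef, numeric(2)))
  expect_gte(mean(rates[, "q_high_low"] > rates[, "q_low_high"]), 0.9)
  expect_lt(median(abs(log10(t(t(rates) / q_true)))), 0.8)
})

test_that("ER is preferred by AIC when switching is truly symmetric", {
  set.seed(25)
  wins <- 0L
  for (r in 1:11) {
    tr <- simulate_tree(120, 30)
    h <- simulate_regime_history(tr, 0.15, 0.15)
    if (length(unique(unclass(h$states))) < 2L) next
    er <- fit_mk(tr, h$states, "ER")
    ard <- fit_mk(tr, h$states, "ARD")
    if (er$AIC < ard$AIC) wins <- wins + 1L
  }
  expect_gt(wins, 5L)
})

test_that("stochastic maps satisfy their structural invariants", {
  set.seed(26)
  tr <- simulate_tree(5, 10)
  st <- rand_regimes(tr)
  mk <- fit_mk(tr, st, "ARD")
  maps <- sample_stochastic_maps(tr, st, mk, n_maps = 100, seed = 1)
  expect_length(maps, 100L)
  for (m in maps) {
    durs <- vapply(m$edge_maps, function(e) sum(e[, 1]), 0)
    expect_lt(max(abs(durs - tr$edge.length)), 1e-9)
    for (e in m$edge_maps)
      if (nrow(e) > 1L) expect_true(all(diff(e[, 2]) != 0))
    for (i in seq_len(5)) {
      k <- which(tr$edge[, 2] == i)
      e <- m$edge_maps[[k]]
      expect_equal(unname(e[nrow(e), 2]), as.numeric(m$tip_states[[i]]))
    }
  }
})

test_that("degenerate rates produce single-state or impossible maps", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  uni <- structure(rep("high", 3), names = tr$tip.label, class = "regimes")
  maps <- sample_stochastic_maps(tr, uni, n_maps = 5, q_lh = 0, q_hl = 0)
  for (m in maps)
    expect_true(all(vapply(m$edge_maps, function(e)
      nrow(e) == 1L && e[1, 2] == 2, TRUE)))
  mixed <- structure(c("low", "high", "low"), names = tr$tip.label,
                     class = "regimes")
  expect_error(sample_stochastic_maps(tr, mixed, n_maps = 1,
                                      q_lh = 0, q_hl = 0), "no valid history")
})

test_that("conditioned branch histories match a conditioned forward oracle", {
  # single branch, low -> low endpoints: compare the mean number of state
  # changes against unconstrained forward simulation filtered on the endpoint
  set.seed(27)
  a <- b <- 0.1; len <- 10
  n_changes <- replicate(4000, {
    p <- elevtraits:::mk_branch_path(1L, 1L, len, a, b)
    length(p$states)
  })
  oracle <- replicate(20000, {
    p <- elevtraits:::mk_forward(1L, len, c(a, b))
    end <- if (length(p$states)) p$states[length(p$states)] else 1L
    if (end == 1L) length(p$states) else NA_integer_
  })
  oracle <- oracle[!is.na(oracle)]
  se <- sqrt(var(oracle) / length(oracle) + var(n_changes) / length(n_changes))
  expect_lt(abs(mean(n_changes) - mean(oracle)), 4 * se)
})

test_that("map node-state frequencies approach the pruning marginals", {
  set.seed(28)
  tr <- simulate_tree(5, 10)
  st <- rand_regimes(tr)
  maps <- sample_stochastic_maps(tr, st, n_maps = 2000, seed = 2,
                                 q_lh = 0.15, q_hl = 0.3)
  emp <- rowMeans(vapply(maps, function(m) m$node_states == 1L,
                         logical(9)))
  marg <- mk_marginals(tr, st, 0.15, 0.3)
  expect_lt(max(abs(emp - marg[, "low"])), 0.05)
})
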