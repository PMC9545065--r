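## Synthetic data: pure-birth trees, forward-simulated regime histories,
## a full experimental-design generator (species x maternal lines x
## temperature treatments with logistic growth series and proportion-valued
## resistance), and the simulation-based validation studies.

#' Simulate a pure-birth (Yule) tree rescaled to a given height
#'
#' Lineages split at rate 1 per lineage; after the n-th tip appears the tree
#' is grown for one more exponential waiting time, then all branch lengths
#' are rescaled so the root-to-tip distance equals `height`. The result is
#' ultrametric by construction.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param height Tree height in mya (default 30); `NULL` keeps the raw
#'   pure-birth time units (rate 1), whose expected height is
#'   \eqn{\sum_{k=2}^{n-1} 1/k + 1/n}.
#' @param seed Optional integer seed.
#' @return A `"phylo"` object with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, height = 30, seed = NULL) {
  if (n_taxa < 2L) stop("need at least 2 taxa")
  if (!is.null(seed)) set.seed(seed)
  ## grow node records: root splits at time 0 into two lineages
  max_nodes <- 2L * n_taxa - 1L
  parent <- integer(max_nodes); etime <- numeric(max_nodes)
  root <- 1L; etime[root] <- 0; parent[root] <- 0L
  nxt <- 3L; parent[2L:3L] <- root
  active <- c(2L, 3L)
  t_now <- 0
  while (length(active) < n_taxa) {
    t_now <- t_now + stats::rexp(1L, length(active))
    v <- active[sample.int(length(active), 1L)]
    etime[v] <- t_now
    c1 <- nxt + 1L; c2 <- nxt + 2L; nxt <- nxt + 2L
    parent[c(c1, c2)] <- v
    active <- c(active[active != v], c1, c2)
  }
  t_end <- t_now + stats::rexp(1L, length(active))
  etime[active] <- t_end
  ## renumber: tips 1..n, root n+1, internals follow
  is_tip <- seq_len(nxt) %in% active
  new_id <- integer(nxt)
  new_id[active] <- seq_len(n_taxa)
  internals <- which(!is_tip)
  internals <- c(root, setdiff(internals, root))
  new_id[internals] <- n_taxa + seq_along(internals)
  child <- which(parent > 0L)
  edge <- cbind(new_id[parent[child]], new_id[child])
  len <- etime[child] - etime[parent[child]]
  if (!is.null(height)) len <- len * height / t_end
  tr <- list(edge = edge, edge.length = len,
             tip.label = paste0("t", seq_len(n_taxa)),
             Nnode = n_taxa - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Forward-simulate a binary regime history on a tree
#'
#' The root state is drawn from the stationary distribution of the 2-state
#' Markov process (flat when both rates are zero) and the chain is simulated
#' forward along every branch. Default rates are realistic strongly
#' asymmetric low/high switching rates per mya.
#'
#' @param tree A rooted `"phylo"`.
#' @param q_lh,q_hl Transition rates per mya (defaults 0.030 and 0.910).
#' @param seed Optional integer seed.
#' @return List: `map` (a `"regime_map"` with the true history), `states`
#'   (tip regimes as a `"regimes"` vector).
#' @export
simulate_regime_history <- function(tree, q_lh = 0.030, q_hl = 0.910,
                                    seed = NULL) {
  if (q_lh < 0 || q_hl < 0) stop("rates must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  p_low <- if (q_lh + q_hl > 0) q_hl / (q_lh + q_hl) else 0.5
  ntip <- ape::Ntip(tree)
  ns <- integer(ntip + tree$Nnode)
  root <- ntip + 1L
  ns[root] <- sample.int(2L, 1L, prob = c(p_low, 1 - p_low))
  po <- ape::reorder.phylo(tree, "postorder")
  orig_idx <- match(paste(po$edge[, 1], po$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  edge_maps <- vector("list", nrow(tree$edge))
  for (k in rev(seq_len(nrow(po$edge)))) {       # preorder
    par <- po$edge[k, 1L]; chd <- po$edge[k, 2L]
    p <- mk_forward(ns[par], po$edge.length[k], c(q_lh, q_hl))
    bounds <- c(0, p$times, po$edge.length[k])
    seg_states <- c(ns[par], p$states)
    ns[chd] <- seg_states[length(seg_states)]
    edge_maps[[orig_idx[k]]] <- cbind(duration = diff(bounds),
                                      state = seg_states)
  }
  tip_states <- stats::setNames(ns[seq_len(ntip)], tree$tip.label)
  map <- structure(list(edge_maps = edge_maps, node_states = ns,
                        tip_states = tip_states,
                        rates = c(q_low_high = q_lh, q_high_low = q_hl)),
                   class = "regime_map")
  states <- structure(REGIME_LEVELS[tip_states], names = tree$tip.label,
                      class = "regimes", threshold_m = NA_real_)
  list(map = map, states = states)
}

#' Simulate a regime history with both regimes represented at the tips
#'
#' Redraws forward-simulated histories until the minority regime holds at
#' least `min_minority_frac` of the tips. Under the strongly asymmetric
#' default rates the stationary high-elevation fraction is small, whereas a
#' comparative study of elevational divergence samples both elevational
#' classes of species; this emulates that stratified taxon coverage.
#'
#' @inheritParams simulate_regime_history
#' @param min_minority_frac Minimum tip fraction of the rarer regime.
#' @param max_tries Attempts before giving up with an error.
#' @return As [simulate_regime_history()].
#' @export
simulate_study_history <- function(tree, q_lh = 0.030, q_hl = 0.910,
                                   min_minority_frac = 0.1, max_tries = 500L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    h <- simulate_regime_history(tree, q_lh, q_hl)
    frac <- min(table(factor(unclass(h$states), levels = REGIME_LEVELS))) /
      ape::Ntip(tree)
    if (frac >= min_minority_frac) return(h)
  }
  stop("no history with minority fraction >= ", min_minority_frac,
       " in ", max_tries, " tries")
}

#' Draw median elevations consistent with regime states
#'
#' Low-regime species get elevations uniform on (400, 1500) m, high-regime
#' species uniform on (1500, 2800) m, matching the range of median
#' elevational occurrence the regimes discretize.
#'
#' @param states A `"regimes"` vector.
#' @param seed Optional integer seed.
#' @return Named numeric vector (m a.s.l.).
#' @export
simulate_elevations <- function(states, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lo <- unclass(states) == "low"
  e <- numeric(length(states))
  e[lo] <- stats::runif(sum(lo), 400, 1500)
  e[!lo] <- stats::runif(sum(!lo), 1500.1, 2800)
  stats::setNames(e, names(states))
}

#' Default configuration for the experimental-design simulator
#'
#' The design mirrors a common-garden macroevolution experiment: `n_taxa`
#' species, two populations of three maternal lines each (six lines, one per
#' block), three temperature treatments, and two sowing rounds. Asymptotic
#' size evolves under a multi-optimum OU process with treatment-specific
#' low/high-elevation optima of realistic magnitude (mm); growth midpoint
#' and scale evolve under single-optimum OU. Resistance scores are
#' logit-normal proportions with regime-dependent means.
#'
#' @param n_taxa Number of species.
#' @param ... Overrides for any default element.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_taxa = 100L, ...) {
  cfg <- list(
    n_taxa = as.integer(n_taxa), tree_height = 30,
    q_lh = 0.030, q_hl = 0.910,
    n_populations = 2L, n_lines_per_population = 3L,
    treatments = c("Frost", "Mild", "Heat"), n_rounds = 2L,
    days = seq(2, 62, by = 4),
    asym_optima = list(Frost = c(low = 57.15, high = 30.44),
                       Mild  = c(low = 64.85, high = 38.72),
                       Heat  = c(low = 70.16, high = 23.65)),
    asym_alpha = 0.2, asym_sigma2 = 4,
    xmid_theta = c(Frost = 28, Mild = 25, Heat = 22),
    xmid_alpha = 0.2, xmid_sigma2 = 1,
    scal_theta = 5, scal_alpha = 0.2, scal_sigma2 = 0.1,
    resist_mean = list(Frost = c(low = 0.45, high = 0.65),
                       Mild  = c(low = 0.60, high = 0.40),
                       Heat  = c(low = 0.50, high = 0.70)),
    resist_logit_sd = 0.5,
    sd_line_asym = 2, sd_line_xmid = 1, sd_round_asym = 0.5,
    sd_resid = 1, seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$n_taxa >= 2L, cfg$n_populations >= 1L,
            cfg$n_lines_per_population >= 1L, cfg$n_rounds >= 1L)
  structure(cfg, class = "synth_config")
}

#' Simulate a full common-garden experiment on a phylogeny
#'
#' Generates the tree, the true regime history, species elevations, species
#' growth parameters per treatment (ASYM under multi-optimum OU with the
#' configured regime-specific optima; XMID and scal under single-optimum
#' OU), maternal-line and sowing-round effects, per-plant logistic growth
#' series with residual noise, and logit-normal resistance scores. The
#' individual table has one row per plant:
#' `n_taxa * n_populations * n_lines_per_population * length(treatments)`
#' rows (1800 at the defaults).
#'
#' @param config A [synth_config()] list.
#' @return List: `individuals`, `growth` (long series table), `tree`, `map`,
#'   `states`, `elevations`, `truth` (all generating species parameters).
#' @export
simulate_experiment <- function(config = synth_config()) {
  cfg <- config
  set.seed(cfg$seed)
  tree <- simulate_tree(cfg$n_taxa, cfg$tree_height)
  hist <- simulate_regime_history(tree, cfg$q_lh, cfg$q_hl)
  elev <- simulate_elevations(hist$states)
  sp <- tree$tip.label

  ## species-level growth parameters per treatment
  truth <- list()
  asym <- xmid <- scal <- matrix(NA_real_, length(sp), length(cfg$treatments),
                                 dimnames = list(sp, cfg$treatments))
  for (tr in cfg$treatments) {
    op <- cfg$asym_optima[[tr]]
    pa <- evo_params("OUM", alpha = cfg$asym_alpha, sigma2 = cfg$asym_sigma2,
                     theta_low = op[["low"]], theta_high = op[["high"]])
    asym[, tr] <- simulate_traits(tree, pa, map = hist$map)$mean
    px <- evo_params("OU1", alpha = cfg$xmid_alpha, sigma2 = cfg$xmid_sigma2,
                     theta = cfg$xmid_theta[[tr]])
    xmid[, tr] <- simulate_traits(tree, px)$mean
    ps <- evo_params("OU1", alpha = cfg$scal_alpha, sigma2 = cfg$scal_sigma2,
                     theta = cfg$scal_theta)
    scal[, tr] <- pmax(simulate_traits(tree, ps)$mean, 0.5)
  }
  asym <- pmax(asym, 1)
  truth$asym <- asym; truth$xmid <- xmid; truth$scal <- scal

  n_lines <- cfg$n_populations * cfg$n_lines_per_population
  grid <- expand.grid(line = seq_len(n_lines), treatment = cfg$treatments,
                      species = sp, stringsAsFactors = FALSE)
  grid$population <- ((grid$line - 1L) %/% cfg$n_lines_per_population) + 1L
  grid$block <- grid$line                     # one maternal line per block
  grid$round <- paste0("S", ((grid$line - 1L) %% cfg$n_rounds) + 1L)
  grid$plant <- paste0(grid$species, "_L", grid$line, "_", grid$treatment)

  si <- match(grid$species, sp)
  ti <- match(grid$treatment, cfg$treatments)
  line_eff_a <- stats::rnorm(nrow(grid), 0, cfg$sd_line_asym)
  line_eff_x <- stats::rnorm(nrow(grid), 0, cfg$sd_line_xmid)
  round_eff <- stats::setNames(stats::rnorm(cfg$n_rounds, 0, cfg$sd_round_asym),
                               paste0("S", seq_len(cfg$n_rounds)))
  grid$ASYM_true <- pmax(asym[cbind(si, ti)] + line_eff_a +
                           round_eff[grid$round], 1)
  grid$XMID_true <- pmax(xmid[cbind(si, ti)] + line_eff_x, 1)
  grid$scal_true <- pmax(scal[cbind(si, ti)], 0.5)

  ## proportion-valued resistance, regime- and treatment-dependent
  reg <- unclass(hist$states)[grid$species]
  pm <- vapply(seq_len(nrow(grid)),
               function(i) cfg$resist_mean[[grid$treatment[i]]][[reg[i]]], 0)
  grid$resistance <- stats::plogis(stats::rnorm(nrow(grid), stats::qlogis(pm),
                                                cfg$resist_logit_sd))

  growth <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    mu <- grid$ASYM_true[i] / (1 + exp((grid$XMID_true[i] - cfg$days) /
                                         grid$scal_true[i]))
    data.frame(plant = grid$plant[i], species = grid$species[i],
               treatment = grid$treatment[i], round = grid$round[i],
               day = cfg$days,
               leaf_length_mm = pmax(mu + stats::rnorm(length(cfg$days), 0,
                                                       cfg$sd_resid), 0),
               stringsAsFactors = FALSE)
  }))
  rownames(growth) <- NULL
  list(individuals = grid, growth = growth, tree = tree, map = hist$map,
       states = hist$states, elevations = elev,
       truth = c(truth, list(config = cfg)))
}

#' Validation study: model selection across SE and optimum-separation grids
#'
#' For every cell of the (measurement-error level x optimum separation x
#' generating model) grid, traits are simulated on the tree (using the true
#' regime map for regime-dependent models), all five models are fitted on
#' that map, and the AICc winner recorded. False positives are cells where
#' the multi-optimum OU model wins although the truth is a different model;
#' false negatives, where the truth is multi-optimum OU but it does not win.
#'
#' @param tree A rooted ultrametric `"phylo"`.
#' @param map A `"regime_map"` on `tree` (e.g. the true simulated history).
#' @param se_levels Measurement-error standard deviations to scan.
#' @param dtheta_levels Optimum separations (trait units) for OUM truth.
#' @param gen_models Generating models, a subset of the five.
#' @param replicates Replicates per cell.
#' @param base_theta Low-elevation optimum / BM and WN location (default 50).
#' @param alpha,sigma2 OU pull and diffusion used for generation.
#' @param seed Optional integer seed.
#' @return Class `"validation_report"`: per-cell winner counts and FP/FN
#'   rates.
#' @export
run_validation_study <- function(tree, map, se_levels = c(0, 2, 8),
                                 dtheta_levels = c(0, 10, 30),
                                 gen_models = c("OUM", "BM1"),
                                 replicates = 20L, base_theta = 50,
                                 alpha = 0.2, sigma2 = 4, seed = NULL) {
  if (replicates < 1L) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(se = se_levels, dtheta = dtheta_levels,
                       model = gen_models, stringsAsFactors = FALSE)
  ## separation only parameterizes OUM truth
  cells <- cells[cells$model == "OUM" | cells$dtheta == dtheta_levels[1L], ]
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    gm <- cells$model[ci]; se <- cells$se[ci]; dt <- cells$dtheta[ci]
    pars <- switch(gm,
      OUM = evo_params("OUM", alpha = alpha, sigma2 = sigma2,
                       theta_low = base_theta, theta_high = base_theta - dt),
      OU1 = evo_params("OU1", alpha = alpha, sigma2 = sigma2,
                       theta = base_theta),
      BM1 = evo_params("BM1", x0 = base_theta, sigma2 = sigma2),
      BMM = evo_params("BMM", x0 = base_theta, sigma2_low = sigma2,
                       sigma2_high = 4 * sigma2),
      WN  = evo_params("WN", mu = base_theta, sigma2 = sigma2))
    winners <- vapply(seq_len(replicates), function(r) {
      dat <- simulate_traits(tree, pars, map = map, se = se)
      fits <- fit_all_evo_models(tree, dat, map = map)
      consensus_best(list(fits))$consensus
    }, "")
    counts <- table(factor(winners, levels = EVO_MODELS))
    data.frame(model = gm, se = se, dtheta = dt, t(as.matrix(counts)),
               fp = if (gm != "OUM") mean(winners == "OUM") else NA_real_,
               fn = if (gm == "OUM") mean(winners != "OUM") else NA_real_)
  })
  structure(do.call(rbind, rows), class = c("validation_report", "data.frame"))
}

#' Consensus stability under random species removal
#'
#' Recomputes the AICc winner after removing a random fraction of species in
#' each replicate (a fresh stochastic map is drawn on the pruned tree from
#' the map's rates) and reports agreement with the full-data winner.
#'
#' @inheritParams run_validation_study
#' @param data Trait data (`species`, `mean`, `se`).
#' @param remove_fraction Fraction removed per replicate (default 1/3).
#' @param replicates Number of replicates.
#' @param seed Optional integer seed.
#' @return List: `full_consensus`, `winners`, `agreement`.
#' @export
run_bootstrap_robustness <- function(tree, data, map, remove_fraction = 1 / 3,
                                     replicates = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  full <- consensus_best(list(fit_all_evo_models(tree, data, map)))$consensus
  n <- ape::Ntip(tree)
  n_drop <- floor(n * remove_fraction)
  states <- structure(REGIME_LEVELS[map$tip_states], names = tree$tip.label,
                      class = "regimes", threshold_m = NA_real_)
  winners <- vapply(seq_len(replicates), function(r) {
    if (n_drop == 0L)
      return(consensus_best(list(fit_all_evo_models(tree, data, map)))$consensus)
    keep <- sample(tree$tip.label, n - n_drop)
    tr <- prune_tree(tree, keep)
    dat <- data[data$species %in% keep, , drop = FALSE]
    mp <- tryCatch(
      sample_stochastic_maps(tr, states[tr$tip.label], n_maps = 1L,
                             q_lh = map$rates[[1]], q_hl = map$rates[[2]])[[1]],
      error = function(e) NULL)
    if (is.null(mp)) return(NA_character_)
    consensus_best(list(fit_all_evo_models(tr, dat, mp)))$consensus
  }, "")
  winners <- winners[!is.na(winners)]
  list(full_consensus = full, winners = winners,
       agreement = mean(winners == full))
}
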