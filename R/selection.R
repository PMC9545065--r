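## AICc model comparison across stochastic maps, phylogenetic half-life,
## the bootstrap significance rule, and treatment contrasts on half-lives.

#' Small-sample Akaike information criterion
#'
#' \eqn{AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)}.
#'
#' @param logLik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of species (observations).
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1 (n = ", n, ", k = ", k, ")")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Consensus best model across stochastic character maps
#'
#' Per map, the winner is the converged model with the lowest AICc (ties
#' broken toward fewer parameters); the consensus is the modal winner across
#' maps. The reported delta-AICc is the median across maps of (winner AICc
#' minus runner-up AICc), so it is negative when the winner leads; the
#' support class is `"among-best"` when its magnitude is at most 2 (model
#' equivalence) and `"clear"` otherwise.
#'
#' @param fits_per_map A list (one element per stochastic map) of named lists
#'   of [fit_evo_model()] results, e.g. from [fit_all_evo_models()].
#' @return An object of class `"model_consensus"`: `consensus`,
#'   `support_class`, `delta_aicc`, vote counts, per-map winners, median OUM
#'   optima and alpha across maps (when available).
#' @export
consensus_best <- function(fits_per_map) {
  if (!length(fits_per_map)) stop("no fitted maps supplied")
  winners <- character(0); deltas <- numeric(0)
  theta_l <- numeric(0); theta_h <- numeric(0); alphas <- numeric(0)
  n_models_pen <- c(WN = 2, BM1 = 2, BMM = 3, OU1 = 3, OUM = 4)
  for (fits in fits_per_map) {
    ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$AICc),
                 TRUE)
    if (!any(ok)) next
    fits <- fits[ok]
    a <- vapply(fits, `[[`, 0, "AICc")
    kk <- vapply(fits, function(f) as.numeric(f$k), 0)
    ord <- order(a, kk)           # ties toward fewer parameters
    winners <- c(winners, names(fits)[ord[1L]])
    if (length(a) > 1L) deltas <- c(deltas, a[ord[1L]] - a[ord[2L]])
    if (!is.null(fits$OUM) && isTRUE(fits$OUM$converged)) {
      theta_l <- c(theta_l, fits$OUM$params$theta_low)
      theta_h <- c(theta_h, fits$OUM$params$theta_high)
    }
    win <- fits[[ord[1L]]]
    if (win$model %in% c("OU1", "OUM")) alphas <- c(alphas, win$params$alpha)
  }
  if (!length(winners)) stop("all model fits failed on every map")
  votes <- sort(table(winners), decreasing = TRUE)
  top <- names(votes)[votes == max(votes)]
  consensus <- top[order(n_models_pen[top])][1L]  # modal; ties by parsimony
  delta <- if (length(deltas)) stats::median(deltas) else NA_real_
  support <- if (is.na(delta)) NA_character_
             else if (abs(delta) <= 2) "among-best" else "clear"
  structure(list(consensus = consensus, support_class = support,
                 delta_aicc = delta, votes = votes, winners = winners,
                 theta_low = if (length(theta_l)) stats::median(theta_l) else NA_real_,
                 theta_high = if (length(theta_h)) stats::median(theta_h) else NA_real_,
                 alpha = if (length(alphas)) stats::median(alphas) else NA_real_,
                 n_maps = length(fits_per_map)),
            class = "model_consensus")
}

#' @export
print.model_consensus <- function(x, ...) {
  cat("Consensus over ", x$n_maps, " stochastic maps: ", x$consensus,
      " (", x$support_class, ", median dAICc to runner-up ",
      round(x$delta_aicc, 2), ")\n", sep = "")
  print(x$votes)
  if (!is.na(x$theta_low))
    cat("median OUM optima: theta_low = ", signif(x$theta_low, 4),
        ", theta_high = ", signif(x$theta_high, 4), "\n", sep = "")
  invisible(x)
}

#' Phylogenetic half-life
#'
#' Time (mya) for the expected trait value to move halfway to the optimum
#' under an OU process: \eqn{t_{1/2} = \ln(2)/\alpha}. Small values indicate
#' fast adaptation; large values, phylogenetic inertia.
#'
#' @param alpha OU pull strength per mya (> 0).
#' @export
half_life <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  log(2) / alpha
}

#' Bootstrap significance rule for half-lives
#'
#' A half-life is called significantly greater than zero when
#' (mean - 1.64 SD) > 0 across bootstrap replicates.
#'
#' @param halflives Numeric vector of bootstrap half-life estimates.
#' @return List with `mean`, `sd`, `significant`.
#' @export
halflife_significance <- function(halflives) {
  m <- mean(halflives); s <- stats::sd(halflives)
  if (length(halflives) == 1L) s <- 0
  list(mean = m, sd = s, significant = (m - 1.64 * s) > 0)
}

#' Bootstrap phylogenetic half-life by random species removal
#'
#' Repeatedly removes a random third of the species, refits the OU model on
#' the pruned tree (policy: OU1, or OUM when regimes are supplied — OUM being
#' the best/among-best model for the trait), and records
#' \eqn{\ln(2)/\hat\alpha}. Significance follows the (mean - 1.64 SD) > 0
#' rule. For OUM, each replicate draws a fresh stochastic map on the pruned
#' tree using the supplied Mk rates.
#'
#' @param tree A rooted ultrametric `"phylo"`.
#' @param data Trait data (`species`, `mean`, `se`).
#' @param model `"OU1"` or `"OUM"`.
#' @param states Regime assignment (required for OUM).
#' @param mk_rates Length-2 vector (q_low_high, q_high_low) used to draw the
#'   per-replicate map for OUM; fitted by [fit_mk()] if omitted.
#' @param remove_fraction Fraction of species removed per replicate (1/3).
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Optional integer seed.
#' @return Class `"halflife_boot"`: `mean`, `sd`, `significant`, `halflives`.
#' @export
bootstrap_half_life <- function(tree, data, model = c("OU1", "OUM"),
                                states = NULL, mk_rates = NULL,
                                remove_fraction = 1 / 3, n_boot = 200L,
                                seed = NULL) {
  model <- match.arg(model)
  if (n_boot < 2L) stop("need at least 2 bootstrap replicates")
  if (model == "OUM") {
    if (is.null(states)) stop("OUM policy requires regime states")
    if (is.null(mk_rates)) {
      mk <- fit_mk(tree, states, "ARD")
      mk_rates <- mk$rates
    }
  }
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  n_drop <- floor(n * remove_fraction)
  hl <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    keep <- sample(tree$tip.label, n - n_drop)
    tr <- prune_tree(tree, keep)
    dat <- data[data$species %in% keep, , drop = FALSE]
    fit <- tryCatch({
      if (model == "OU1") fit_evo_model("OU1", tr, dat)
      else {
        mp <- sample_stochastic_maps(tr, states[tr$tip.label], n_maps = 1L,
                                     q_lh = mk_rates[[1]], q_hl = mk_rates[[2]])[[1]]
        fit_evo_model("OUM", tr, dat, map = mp)
      }
    }, error = function(e) NULL)
    if (!is.null(fit) && isTRUE(fit$converged))
      hl[b] <- half_life(fit$params$alpha)
  }
  hl <- hl[is.finite(hl)]
  if (length(hl) < 2L) stop("too few successful bootstrap refits")
  sig <- halflife_significance(hl)
  structure(c(sig, list(halflives = hl, n_boot = n_boot, model = model)),
            class = "halflife_boot")
}

#' @export
print.halflife_boot <- function(x, ...) {
  cat("Bootstrap phylogenetic half-life (", x$model, ", ",
      length(x$halflives), "/", x$n_boot, " replicates): ",
      round(x$mean, 2), " +/- ", round(x$sd, 2), " mya",
      if (x$significant) " *", "\n", sep = "")
  invisible(x)
}

#' Treatment contrasts on phylogenetic half-lives
#'
#' Linear mixed model on log half-life with treatment as fixed effect
#' (baseline `"Mild"`) and trait as a random intercept, fitted by maximum
#' likelihood; 90 percent percentile intervals come from bootstrapping over
#' traits. A contrast of \eqn{\log(0.5) \approx -0.693} corresponds to a
#' 50 percent reduction of average half-life relative to the baseline.
#'
#' @param halflives data.frame with columns `trait`, `treatment`, `t_half`
#'   (mya, > 0).
#' @param baseline Baseline treatment (default `"Mild"`).
#' @param n_boot Bootstrap-over-traits replicates (default 500).
#' @param seed Optional integer seed.
#' @return Class `"halflife_contrast"`: `contrasts` (log scale), `ci`,
#'   `percent_change`, variance components.
#' @export
treatment_halflife_contrast <- function(halflives, baseline = "Mild",
                                        n_boot = 500L, seed = NULL) {
  req <- c("trait", "treatment", "t_half")
  if (!all(req %in% names(halflives)))
    stop("need columns: ", paste(req, collapse = ", "))
  if (length(unique(halflives$treatment)) < 2L)
    stop("need half-lives in at least 2 treatments")
  if (length(unique(halflives$trait)) < 3L)
    stop("need at least 3 traits")
  if (any(halflives$t_half <= 0)) stop("half-lives must be positive")

  fit_one <- function(d) {
    y <- log(d$t_half)
    treat <- stats::relevel(factor(d$treatment), ref = baseline)
    X <- stats::model.matrix(~ treat)
    colnames(X) <- sub("^treat", "", colnames(X))
    B <- stats::model.matrix(~ 0 + factor(d$trait))
    f <- lmm_ml(y, X, list(trait = B))
    f$beta <- stats::setNames(f$beta, colnames(X))
    f
  }
  fit <- fit_one(halflives)
  est <- fit$beta

  if (!is.null(seed)) set.seed(seed)
  traits <- unique(halflives$trait)
  boot <- matrix(NA_real_, length(est), n_boot)
  for (b in seq_len(n_boot)) {
    tb <- sample(traits, replace = TRUE)
    d <- do.call(rbind, lapply(seq_along(tb), function(i) {
      di <- halflives[halflives$trait == tb[i], , drop = FALSE]
      di$trait <- paste0(tb[i], "_", i)   # resampled traits stay distinct
      di
    }))
    fb <- tryCatch(fit_one(d), error = function(e) NULL)
    if (!is.null(fb) && length(fb$beta) == length(est)) boot[, b] <- fb$beta
  }
  boot <- boot[, colSums(is.na(boot)) == 0L, drop = FALSE]
  ci <- if (ncol(boot) > 1L) t(apply(boot, 1L, stats::quantile, c(0.05, 0.95)))
        else cbind(`5%` = est, `95%` = est)
  rownames(ci) <- names(est)
  contrasts <- est[-1L]
  structure(list(contrasts = contrasts,
                 percent_change = 100 * (exp(contrasts) - 1),
                 intercept = est[[1L]], ci = ci,
                 vc = c(trait = fit$sigma2[[1]], resid = fit$sigma2e),
                 logLik = fit$logLik, baseline = baseline,
                 n_boot = ncol(boot)),
            class = "halflife_contrast")
}

#' @export
print.halflife_contrast <- function(x, digits = 3, ...) {
  cat("Treatment contrasts on log half-life (baseline ", x$baseline, ")\n",
      sep = "")
  tab <- data.frame(log_contrast = signif(x$contrasts, digits),
                    pct_change = signif(x$percent_change, digits),
                    lower90 = signif(x$ci[-1L, 1L], digits),
                    upper90 = signif(x$ci[-1L, 2L], digits))
  print(tab)
  invisible(x)
}
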