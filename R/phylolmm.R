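## Maximum-likelihood linear mixed models with arbitrary Gaussian random
## effects supplied as low-rank factors, V = sigma_e^2 (I + sum_i g_i B_i B_i').
## Fixed effects and the residual variance are profiled analytically; the
## variance ratios g_i are optimized on the log scale. All solves go through
## the matrix-determinant/Woodbury identities on crossproducts precomputed
## once, so a likelihood evaluation costs O(q^3) with q = total random-effect
## rank, independent of the number of observations.

lmm_ml <- function(y, X, B_list, starts = NULL, reml = FALSE) {
  n <- length(y)
  p <- ncol(X)
  m <- length(B_list)
  Z <- if (m) do.call(cbind, B_list) else matrix(0, n, 0L)
  qi <- vapply(B_list, ncol, 0L)
  gidx <- rep(seq_len(m), qi)
  CZZ <- crossprod(Z); CZX <- crossprod(Z, X); CZy <- drop(crossprod(Z, y))
  CXX <- crossprod(X); CXy <- drop(crossprod(X, y)); Cyy <- sum(y^2)

  eval_g <- function(g) {
    s <- sqrt(g)[gidx]
    M <- diag(ncol(Z)) + CZZ * tcrossprod(s)
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    GX <- CZX * s; Gy <- CZy * s
    W <- backsolve(ch, cbind(GX, Gy), transpose = TRUE)
    WX <- W[, seq_len(p), drop = FALSE]; Wy <- W[, p + 1L]
    XtVX <- CXX - crossprod(WX)
    XtVy <- CXy - drop(crossprod(WX, Wy))
    yVy <- Cyy - sum(Wy^2)
    beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    rss <- yVy - sum(beta * XtVy)
    if (rss <= 0) return(NULL)
    if (reml) {
      sigma2e <- rss / (n - p)
      chx <- tryCatch(chol(XtVX), error = function(e) NULL)
      if (is.null(chx)) return(NULL)
      ll <- -0.5 * ((n - p) * log(2 * pi * sigma2e) +
                      2 * sum(log(diag(ch))) +
                      2 * sum(log(diag(chx))) + (n - p))
    } else {
      sigma2e <- rss / n
      ll <- -0.5 * (n * log(2 * pi * sigma2e) + 2 * sum(log(diag(ch))) + n)
    }
    list(beta = drop(beta), sigma2e = sigma2e, logLik = ll, XtVX = XtVX)
  }
  if (m == 0L) {
    beta <- drop(solve(CXX, CXy))
    rss <- Cyy - sum(beta * CXy)
    s2 <- rss / n
    return(list(beta = beta, sigma2e = s2,
                logLik = -0.5 * (n * log(2 * pi * s2) + n),
                gamma = numeric(0), sigma2 = numeric(0), n = n, p = p))
  }
  nll <- function(lg) {
    r <- eval_g(exp(lg))
    if (is.null(r) || !is.finite(r$logLik)) 1e10 else -r$logLik
  }
  if (is.null(starts))
    starts <- as.matrix(expand.grid(rep(list(log(c(1e-4, 0.3, 3))), m)))
  starts <- matrix(starts, ncol = m)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    op <- tryCatch(stats::optim(starts[i, ], nll, method = "L-BFGS-B",
                                lower = -25, upper = 15,
                                control = list(factr = 1e5)),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) stop("mixed-model ML failed from every start")
  g <- exp(best$par)
  r <- eval_g(g)
  c(r, list(gamma = unname(g), sigma2 = unname(g * r$sigma2e), n = n, p = p))
}

#' Fit a phylogenetic linear mixed model by maximum likelihood
#'
#' Models a species-level trait observed per treatment and sowing round:
#' fixed effects are the treatment factor (contrasts against a stated
#' baseline), mean-centered median elevation, and their interaction; random
#' effects are a sowing-round intercept and a phylogenetic species effect
#' with covariance proportional to the phylogenetic covariance C (scaled to
#' unit height internally). Responses can be analysed on the identity, log,
#' or logit scale; logit responses in \[0, 1\] are shrunk away from the
#' boundary by \eqn{y' = (y(n-1)+0.5)/n} first. Inference on the fixed
#' effects uses a parametric bootstrap: 90 percent percentile intervals and
#' probability-of-direction significance tiers.
#'
#' @param data data.frame with columns `species`, `treatment`, `round`,
#'   `value`, and `elevation` (median elevation, m a.s.l., constant within
#'   species).
#' @param tree A rooted `"phylo"` covering all species in `data`.
#' @param transform `"identity"`, `"log"`, or `"logit"`.
#' @param baseline Treatment baseline for contrasts (default `"Mild"`; use
#'   `"Frost"` for tolerance traits).
#' @param include_phylogeny Include the phylogenetic random effect?
#' @param n_boot Parametric bootstrap draws for intervals (default 500).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `"phylo_lmm"` with elements `beta`, `ci`
#'   (90 percent), `tiers`, `vc` (named variance components), `logLik`,
#'   `AICc`, `n`, and the bootstrap draws.
#' @export
fit_phylo_lmm <- function(data, tree, transform = c("identity", "log", "logit"),
                          baseline = "Mild", include_phylogeny = TRUE,
                          n_boot = 500L, seed = NULL) {
  transform <- match.arg(transform)
  req <- c("species", "treatment", "round", "value", "elevation")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  sp <- intersect(tree$tip.label, unique(data$species))
  if (length(sp) < 10L) stop("need at least 10 species shared with the tree")
  data <- data[data$species %in% sp, , drop = FALSE]
  if (!(baseline %in% data$treatment))
    stop("baseline treatment '", baseline, "' absent from data")

  y <- switch(transform,
    identity = data$value,
    log = {
      if (any(data$value <= 0)) {
        bad <- which(data$value <= 0)
        stop("log transform needs positive values; offending rows: ",
             paste(utils::head(bad, 5L), collapse = ", "))
      }
      log(data$value)
    },
    logit = {
      if (any(data$value < 0 | data$value > 1)) {
        bad <- which(data$value < 0 | data$value > 1)
        stop("logit transform needs values in [0, 1]; offending rows: ",
             paste(utils::head(bad, 5L), collapse = ", "))
      }
      nn <- nrow(data)
      stats::qlogis((data$value * (nn - 1) + 0.5) / nn)
    })

  treat <- stats::relevel(factor(data$treatment), ref = baseline)
  # center on the mean of the species-level median elevations
  elev_c <- data$elevation - mean(tapply(data$elevation, data$species, mean))
  X <- stats::model.matrix(~ treat * elev_c)
  colnames(X) <- sub("^treat", "", colnames(X))

  rnd <- factor(data$round)
  B_round <- stats::model.matrix(~ 0 + rnd)
  Cn <- phylo_covariance(prune_tree(tree, sp))
  Cn <- Cn / max(Cn)
  Lc <- t(chol(Cn + diag(1e-10, nrow(Cn))))
  Zs <- stats::model.matrix(~ 0 + factor(data$species, levels = rownames(Cn)))
  B_phylo <- Zs %*% Lc

  B_list <- if (include_phylogeny) list(phylo = B_phylo, round = B_round)
            else list(round = B_round)
  fit <- lmm_ml(y, X, B_list)
  m <- length(B_list)
  k <- ncol(X) + m + 1L
  vc <- c(if (include_phylogeny) c(phylo = fit$sigma2[1]),
          round = fit$sigma2[[if (include_phylogeny) 2L else 1L]],
          resid = fit$sigma2e)

  boot <- NULL
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    mu_hat <- drop(X %*% fit$beta)
    # bootstrap datasets are generated at REML variance components: ML
    # components are biased downward and would make the intervals undercover
    gen <- tryCatch(lmm_ml(y, X, B_list, reml = TRUE,
                           starts = log(pmax(fit$gamma, 1e-8))),
                    error = function(e) fit)
    sds <- sqrt(gen$sigma2)
    sd_e <- sqrt(gen$sigma2e)
    boot <- matrix(NA_real_, ncol(X), n_boot,
                   dimnames = list(colnames(X), NULL))
    for (b in seq_len(n_boot)) {
      ystar <- mu_hat + stats::rnorm(length(y), 0, sd_e)
      for (j in seq_len(m))
        ystar <- ystar + drop(B_list[[j]] %*%
                                stats::rnorm(ncol(B_list[[j]]), 0, sds[j]))
      fb <- tryCatch(lmm_ml(ystar, X, B_list,
                            starts = log(pmax(fit$gamma, 1e-8))),
                     error = function(e) NULL)
      if (!is.null(fb)) boot[, b] <- fb$beta
    }
    boot <- boot[, colSums(is.na(boot)) == 0L, drop = FALSE]
  }
  ci <- if (!is.null(boot) && ncol(boot) > 1L)
    t(apply(boot, 1L, stats::quantile, c(0.05, 0.95))) else
    cbind(`5%` = fit$beta, `95%` = fit$beta)
  out <- structure(list(beta = stats::setNames(fit$beta, colnames(X)),
                        ci = ci, boot = boot, vc = vc,
                        logLik = fit$logLik, k = k,
                        AICc = aicc(fit$logLik, k, length(y)),
                        n = length(y), n_species = length(sp),
                        transform = transform, baseline = baseline,
                        include_phylogeny = include_phylogeny),
                   class = "phylo_lmm")
  out$tiers <- significance_tiers(out)
  out
}

#' @export
print.phylo_lmm <- function(x, digits = 3, ...) {
  cat("Phylogenetic linear mixed model (ML), ", x$n, " obs, ",
      x$n_species, " species\n", sep = "")
  cat("  transform: ", x$transform, ", baseline: ", x$baseline,
      if (!x$include_phylogeny) ", phylogeny excluded", "\n", sep = "")
  tab <- data.frame(estimate = signif(x$beta, digits),
                    lower90 = signif(x$ci[, 1], digits),
                    upper90 = signif(x$ci[, 2], digits),
                    tier = x$tiers)
  print(tab)
  cat("variance components: ",
      paste(names(x$vc), signif(x$vc, digits), sep = " = ", collapse = ", "),
      "\n  logLik = ", round(x$logLik, 3), ", AICc = ", round(x$AICc, 2),
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.phylo_lmm <- function(object, ...) object$beta

#' @export
logLik.phylo_lmm <- function(object, ...) {
  structure(object$logLik, df = object$k, class = "logLik")
}

#' Does the phylogeny improve the mixed model?
#'
#' Fits the model with and without the phylogenetic random effect and
#' returns the AICc difference (with minus without); negative values favour
#' keeping the phylogenetic effect.
#'
#' @inheritParams fit_phylo_lmm
#' @return Scalar AICc difference, with both fits as attributes.
#' @export
compare_phylogeny <- function(data, tree, transform = "identity",
                              baseline = "Mild") {
  f1 <- fit_phylo_lmm(data, tree, transform, baseline,
                      include_phylogeny = TRUE, n_boot = 0L)
  f0 <- fit_phylo_lmm(data, tree, transform, baseline,
                      include_phylogeny = FALSE, n_boot = 0L)
  structure(f1$AICc - f0$AICc, with_phylo = f1, without_phylo = f0)
}

#' Probability-of-direction significance tiers
#'
#' For each fixed effect, pd is the larger of the fractions of bootstrap
#' draws above/below zero; tiers: pd > 99.95 percent `***`, > 99.5 `**`,
#' > 97.5 `*`, > 95 `(.)`, else `ns`.
#'
#' @param fit A `"phylo_lmm"` fit with stored bootstrap draws.
#' @return Character vector of tiers, one per coefficient.
#' @export
significance_tiers <- function(fit) {
  if (is.null(fit$boot) || ncol(fit$boot) == 0L)
    return(rep("ns", length(fit$beta)))
  pd <- unname(apply(fit$boot, 1L, function(d) max(mean(d > 0), mean(d < 0))))
  ifelse(pd > 0.9995, "***",
         ifelse(pd > 0.995, "**",
                ifelse(pd > 0.975, "*",
                       ifelse(pd > 0.95, "(.)", "ns"))))
}
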