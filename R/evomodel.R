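## Trait-evolution models on a phylogeny with species-mean measurement error:
## WN  - white noise, traits independent of phylogeny (mu, sigma2)
## BM1 - Brownian motion, one diffusion rate (x0, sigma2)
## BMM - Brownian motion with regime-specific rates (x0, sigma2_low/high)
## OU1 - single-optimum Ornstein-Uhlenbeck (alpha, sigma2, theta)
## OUM - multi-optimum OU, one alpha/sigma2, regime-specific optima
##       (alpha, sigma2, theta_low, theta_high), regimes from a stochastic map.
## The root state of OU models is pinned to the optimum of the root's regime,
## so free-parameter counts are k = {WN:2, BM1:2, BMM:3, OU1:3, OUM:4}.

EVO_MODELS <- c("WN", "BM1", "BMM", "OU1", "OUM")

#' Construct trait-evolution model parameters
#'
#' @param model One of `"WN"`, `"BM1"`, `"BMM"`, `"OU1"`, `"OUM"`.
#' @param mu White-noise mean (WN).
#' @param x0 Root state (BM1/BMM).
#' @param sigma2 Diffusion variance per mya (all but BMM).
#' @param sigma2_low,sigma2_high Regime-specific diffusion variances (BMM).
#' @param alpha OU pull strength per mya (> 0; OU1/OUM).
#' @param theta OU1 optimum.
#' @param theta_low,theta_high OUM optima for the low/high regimes.
#' @return A list of class `"evo_params"`.
#' @export
evo_params <- function(model, mu = NULL, x0 = NULL, sigma2 = NULL,
                       sigma2_low = NULL, sigma2_high = NULL, alpha = NULL,
                       theta = NULL, theta_low = NULL, theta_high = NULL) {
  model <- match.arg(model, EVO_MODELS)
  need <- switch(model,
    WN  = list(mu = mu, sigma2 = sigma2),
    BM1 = list(x0 = x0, sigma2 = sigma2),
    BMM = list(x0 = x0, sigma2_low = sigma2_low, sigma2_high = sigma2_high),
    OU1 = list(alpha = alpha, sigma2 = sigma2, theta = theta),
    OUM = list(alpha = alpha, sigma2 = sigma2,
               theta_low = theta_low, theta_high = theta_high))
  miss <- names(need)[vapply(need, is.null, TRUE)]
  if (length(miss))
    stop(model, " requires parameters: ", paste(miss, collapse = ", "))
  for (nm in grep("sigma2", names(need), value = TRUE))
    if (need[[nm]] <= 0) stop(nm, " must be > 0")
  if (!is.null(need$alpha) && need$alpha <= 0) stop("alpha must be > 0")
  structure(c(list(model = model), need), class = "evo_params")
}

## OUM mean design: n x 2 matrix of optimum weights per tip; row i gives the
## coefficients of (theta_low, theta_high) in E[x_i]. Includes the root term
## exp(-alpha*T) assigned to the root regime (root state = optimum of the
## root's regime). Rows sum to 1.
oum_weights <- function(tree, map, alpha, segs = NULL, depths = NULL) {
  if (is.null(segs)) segs <- map_tip_segments(tree, map)
  if (is.null(depths)) depths <- tip_depths(tree)
  W <- matrix(0, length(segs), 2L,
              dimnames = list(names(segs), REGIME_LEVELS))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    Tt <- depths[i]
    w <- exp(-alpha * (Tt - s[, "end"])) - exp(-alpha * (Tt - s[, "start"]))
    for (st in 1:2) W[i, st] <- sum(w[s[, "state"] == st])
    W[i, s[1L, "state"]] <- W[i, s[1L, "state"]] + exp(-alpha * Tt)
  }
  W
}

#' Expected species trait values under an evolutionary model
#'
#' For OUM, the expectation integrates the regime-specific optima along each
#' root-to-tip lineage of the stochastic map, weighting each history segment
#' \eqn{[t_0, t_1]} by \eqn{e^{-\alpha(T-t_1)} - e^{-\alpha(T-t_0)}}, plus the
#' root term \eqn{x_0 e^{-\alpha T}} with the root state at the root regime's
#' optimum. WN/BM models give constant vectors; OU1 collapses to its optimum.
#'
#' @param tree A rooted `"phylo"` object.
#' @param params An [evo_params()] object.
#' @param map A `"regime_map"` (required for OUM, ignored otherwise).
#' @return Named numeric vector over tips.
#' @export
model_mean <- function(tree, params, map = NULL) {
  n <- ape::Ntip(tree)
  v <- switch(params$model,
    WN  = rep(params$mu, n),
    BM1 = ,
    BMM = rep(params$x0, n),
    OU1 = rep(params$theta, n),
    OUM = {
      if (is.null(map)) stop("OUM requires a stochastic map")
      drop(oum_weights(tree, map, params$alpha) %*%
             c(params$theta_low, params$theta_high))
    })
  names(v) <- tree$tip.label
  v
}

#' Model covariance of species trait values
#'
#' WN: \eqn{\sigma^2 I}. BM1: \eqn{\sigma^2 C} with C the phylogenetic
#' covariance. BMM: each branch contributes its regime-specific rate times
#' the time spent in that regime, accumulated root-to-MRCA. OU1/OUM (shared
#' alpha and sigma2): \eqn{V_{ij} = \frac{\sigma^2}{2\alpha}
#' e^{-2\alpha(T - s_{ij})}(1 - e^{-2\alpha s_{ij}})} with \eqn{s_{ij}}
#' the shared time (requires an ultrametric tree). Known measurement error
#' enters as `+ diag(se^2)`.
#'
#' @inheritParams model_mean
#' @param se Per-species standard errors of the species means (scalar or
#'   named vector; default 0).
#' @return Species-by-species covariance matrix.
#' @export
model_covariance <- function(tree, params, map = NULL, se = 0) {
  n <- ape::Ntip(tree)
  se <- expand_se(se, tree$tip.label)
  V <- switch(params$model,
    WN  = diag(params$sigma2, n),
    BM1 = params$sigma2 * phylo_covariance(tree),
    BMM = {
      if (is.null(map)) stop("BMM requires a stochastic map")
      Cs <- regime_shared_times(tree, map)
      params$sigma2_low * Cs$low + params$sigma2_high * Cs$high
    },
    OU1 = ,
    OUM = {
      if (!is_ultrametric(tree, tol = 1e-6))
        stop("OU covariance requires an ultrametric tree")
      C <- phylo_covariance(tree)
      Tt <- max(C)
      a <- params$alpha
      params$sigma2 / (2 * a) * exp(-2 * a * (Tt - C)) * (-expm1(-2 * a * C))
    })
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  diag(V) <- diag(V) + se^2
  V
}

## shared time in each regime for every tip pair (root-to-MRCA, under a map)
regime_shared_times <- function(tree, map) {
  npt <- map_node_path_times(tree, map)
  M <- ape::mrca(tree)
  list(low = matrix(npt[M, 1L], nrow(M), ncol(M), dimnames = dimnames(M)),
       high = matrix(npt[M, 2L], nrow(M), ncol(M), dimnames = dimnames(M)))
}

expand_se <- function(se, tips) {
  if (length(se) == 1L) se <- stats::setNames(rep(se, length(tips)), tips)
  if (is.null(names(se))) {
    if (length(se) != length(tips)) stop("'se' length does not match tips")
    names(se) <- tips
  }
  miss <- setdiff(tips, names(se))
  if (length(miss)) stop("no SE for species: ", paste(miss, collapse = ", "))
  if (any(se < 0, na.rm = TRUE)) stop("SEs must be non-negative")
  se[tips]
}

## multivariate-normal log density via Cholesky; informative error if singular
mvn_loglik <- function(y, mu, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
    stop("model covariance is singular (smallest eigenvalue ",
         signif(ev, 3), ")")
  }
  r <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
}

#' Log-likelihood of species trait means under an evolutionary model
#'
#' Multivariate-normal log density of the species means with expectation
#' [model_mean()] and covariance [model_covariance()] (including the
#' measurement-error diagonal).
#'
#' @inheritParams model_covariance
#' @param data Trait data: a data.frame with columns `species`, `mean` and
#'   optionally `se`, or a named numeric vector of species means.
#' @export
model_loglik <- function(tree, params, data, map = NULL) {
  td <- as_trait_data(data, tree$tip.label)
  mu <- model_mean(tree, params, map)
  V <- model_covariance(tree, params, map, se = td$se)
  mvn_loglik(td$mean, mu, V)
}

## normalize trait data to list(mean, se) aligned with the tips
as_trait_data <- function(data, tips) {
  if (is.data.frame(data)) {
    if (!all(c("species", "mean") %in% names(data)))
      stop("trait data needs columns 'species' and 'mean'")
    miss <- setdiff(tips, data$species)
    if (length(miss))
      stop("no trait value for species: ", paste(miss, collapse = ", "))
    i <- match(tips, data$species)
    se <- if ("se" %in% names(data)) data$se[i] else rep(0, length(tips))
    se[is.na(se)] <- 0
    list(mean = stats::setNames(data$mean[i], tips),
         se = stats::setNames(se, tips))
  } else if (is.numeric(data)) {
    list(mean = expand_named(data, tips), se = stats::setNames(rep(0, length(tips)), tips))
  } else stop("unsupported trait data")
}

expand_named <- function(x, tips) {
  if (is.null(names(x))) { names(x) <- tips; return(x) }
  miss <- setdiff(tips, names(x))
  if (length(miss)) stop("no value for species: ", paste(miss, collapse = ", "))
  x[tips]
}

## --- maximum-likelihood fitting --------------------------------------------

## Profiled log-likelihood: location parameters (mu/x0/theta) solved by GLS
## for a given covariance V and mean design D.
gls_profile <- function(y, D, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Dy <- backsolve(ch, cbind(D, y), transpose = TRUE)
  Dt <- Dy[, seq_len(ncol(D)), drop = FALSE]
  yt <- Dy[, ncol(D) + 1L]
  XtX <- crossprod(Dt)
  qr_ok <- tryCatch(solve(XtX, crossprod(Dt, yt)), error = function(e) NULL)
  if (is.null(qr_ok)) return(NULL)
  beta <- drop(qr_ok)
  r <- yt - Dt %*% beta
  ll <- -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
  list(beta = beta, logLik = ll)
}

#' Fit a trait-evolution model by maximum likelihood
#'
#' Location parameters (mean, root state, optima) are profiled analytically
#' by generalized least squares; the covariance parameters are optimized on
#' the log scale (bounded quasi-Newton), with a 10-point multi-start grid on
#' log(alpha) over \[1e-4, 100\] for the OU models. Measurement error (`se`
#' column of `data`) enters the covariance as a known diagonal.
#'
#' @inheritParams model_loglik
#' @param model One of `"WN"`, `"BM1"`, `"BMM"`, `"OU1"`, `"OUM"`.
#' @param map A `"regime_map"` (required for BMM/OUM).
#' @param alpha_grid Multi-start values for log(alpha) (OU models).
#' @return An object of class `"evo_fit"`: `params`, `logLik`, `k`, `AICc`,
#'   `n`, `converged`.
#' @export
fit_evo_model <- function(model, tree, data, map = NULL,
                          alpha_grid = 10^seq(-4, 2, length.out = 10)) {
  model <- match.arg(model, EVO_MODELS)
  td <- as_trait_data(data, tree$tip.label)
  y <- td$mean; se <- td$se
  n <- length(y)
  k <- c(WN = 2L, BM1 = 2L, BMM = 3L, OU1 = 3L, OUM = 4L)[[model]]
  if (n <= k + 1L) stop("need more than k + 1 = ", k + 1L, " species")
  if (model %in% c("BMM", "OUM") && is.null(map))
    stop(model, " requires a stochastic map")

  vy <- stats::var(y)
  if (!is.finite(vy) || vy < 1e-12 * max(1, mean(y)^2)) {
    return(evo_fit_failed(model, n, k, "trait variance is (near) zero"))
  }
  C <- phylo_covariance(tree)
  Tt <- max(C)
  SE2 <- se^2
  ones <- matrix(1, n, 1L)
  Cs <- if (model == "BMM") regime_shared_times(tree, map) else NULL
  if (model %in% c("OU1", "OUM") && !is_ultrametric(tree, tol = 1e-6))
    stop("OU models require an ultrametric tree")
  segs <- if (model == "OUM") map_tip_segments(tree, map) else NULL
  depths <- if (model == "OUM") tip_depths(tree) else NULL

  build <- function(par) {
    switch(model,
      WN  = list(V = diag(exp(par[1]), n) + diag(SE2), D = ones),
      BM1 = list(V = exp(par[1]) * C + diag(SE2), D = ones),
      BMM = list(V = exp(par[1]) * Cs$low + exp(par[2]) * Cs$high + diag(SE2),
                 D = ones),
      OU1 = {
        a <- exp(par[1])
        list(V = exp(par[2]) / (2 * a) * exp(-2 * a * (Tt - C)) *
               (-expm1(-2 * a * C)) + diag(SE2), D = ones)
      },
      OUM = {
        a <- exp(par[1])
        list(V = exp(par[2]) / (2 * a) * exp(-2 * a * (Tt - C)) *
               (-expm1(-2 * a * C)) + diag(SE2),
             D = oum_weights(tree, map, a, segs, depths))
      })
  }
  nll <- function(par) {
    m <- build(par)
    pr <- gls_profile(y, m$D, m$V)
    if (is.null(pr) || !is.finite(pr$logLik)) return(1e10)
    -pr$logLik
  }

  starts <- switch(model,
    WN  = ,
    BM1 = matrix(log(vy / c(0.1, 1, 10) / max(Tt, 1)), ncol = 1L),
    BMM = {
      s0 <- log(vy / Tt)
      rbind(c(s0, s0), c(s0 + 2, s0 - 2), c(s0 - 2, s0 + 2))
    },
    OU1 = ,
    OUM = cbind(log(alpha_grid), log(2 * alpha_grid * vy)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    op <- tryCatch(
      stats::optim(starts[i, ], nll, method = "L-BFGS-B",
                   lower = -30, upper = 30,
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(op) && op$value < 1e9 &&
        (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best))
    return(evo_fit_failed(model, n, k, "all optimizer starts failed"))
  m <- build(best$par)
  pr <- gls_profile(y, m$D, m$V)
  converged <- TRUE
  if (model == "OUM") {
    # both regimes must actually be represented along the lineages
    if (min(colSums(abs(m$D))) < 1e-8 || qr(m$D)$rank < 2L) converged <- FALSE
  }
  params <- switch(model,
    WN  = evo_params("WN", mu = pr$beta[1], sigma2 = exp(best$par[1])),
    BM1 = evo_params("BM1", x0 = pr$beta[1], sigma2 = exp(best$par[1])),
    BMM = evo_params("BMM", x0 = pr$beta[1],
                     sigma2_low = exp(best$par[1]),
                     sigma2_high = exp(best$par[2])),
    OU1 = evo_params("OU1", alpha = exp(best$par[1]),
                     sigma2 = exp(best$par[2]), theta = pr$beta[1]),
    OUM = evo_params("OUM", alpha = exp(best$par[1]),
                     sigma2 = exp(best$par[2]),
                     theta_low = pr$beta[1], theta_high = pr$beta[2]))
  structure(list(model = model, params = params, logLik = pr$logLik,
                 k = k, AICc = aicc(pr$logLik, k, n), n = n,
                 converged = converged),
            class = "evo_fit")
}

evo_fit_failed <- function(model, n, k, reason) {
  structure(list(model = model, params = NULL, logLik = NA_real_, k = k,
                 AICc = NA_real_, n = n, converged = FALSE, reason = reason),
            class = "evo_fit")
}

#' @export
print.evo_fit <- function(x, digits = 4, ...) {
  cat("Trait-evolution model ", x$model, " (", x$n, " species)\n", sep = "")
  if (!x$converged) cat("  NOT converged",
                        if (!is.null(x$reason)) paste0(": ", x$reason), "\n")
  if (!is.null(x$params)) {
    p <- unlist(x$params[-1])
    cat("  ", paste(names(p), signif(p, digits), sep = " = ",
                    collapse = ", "), "\n", sep = "")
  }
  cat("  logLik = ", round(x$logLik, 3), ", k = ", x$k,
      ", AICc = ", round(x$AICc, 3), "\n", sep = "")
  invisible(x)
}

#' @export
logLik.evo_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, class = "logLik")
}

#' @export
coef.evo_fit <- function(object, ...) unlist(object$params[-1])

#' Fit all five trait-evolution models on one dataset
#'
#' @inheritParams fit_evo_model
#' @param models Subset of the five model names.
#' @return Named list of `"evo_fit"` objects.
#' @export
fit_all_evo_models <- function(tree, data, map = NULL, models = EVO_MODELS) {
  fits <- lapply(models, function(m)
    tryCatch(fit_evo_model(m, tree, data, map),
             error = function(e) evo_fit_failed(
               m, ape::Ntip(tree),
               c(WN = 2L, BM1 = 2L, BMM = 3L, OU1 = 3L, OUM = 4L)[[m]],
               conditionMessage(e))))
  names(fits) <- models
  fits
}

#' Simulate species trait means under an evolutionary model
#'
#' One multivariate-normal draw with the model mean and covariance (without
#' measurement error), plus independent noise with standard deviation `se`
#' per species.
#'
#' @inheritParams model_covariance
#' @param seed Optional integer seed.
#' @return data.frame with columns `species`, `mean`, `se`.
#' @export
simulate_traits <- function(tree, params, map = NULL, se = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  se <- expand_se(se, tree$tip.label)
  mu <- model_mean(tree, params, map)
  V <- model_covariance(tree, params, map, se = 0)
  n <- length(mu)
  y <- mu
  if (max(abs(V)) > 0) {
    ch <- chol(V + diag(1e-12 * max(diag(V)), n))
    y <- y + drop(crossprod(ch, stats::rnorm(n)))
  }
  y <- y + stats::rnorm(n, 0, se)
  data.frame(species = tree$tip.label, mean = unname(y), se = unname(se),
             stringsAsFactors = FALSE)
}
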