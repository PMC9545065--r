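## Growth-curve traits from individual plant records: three-parameter
## logistic fits (ASYM, XMID, scal; MGR = 1/scal), initial growth rate,
## the (-)XMID sign convention, stress tolerances, and hierarchical
## aggregation to species means with measurement error.

#' Fit a three-parameter logistic growth curve
#'
#' Least-squares fit of \eqn{y(t) = ASYM / (1 + \exp((XMID - t)/scal))} to a
#' single plant's leaf-length series. Uses the self-starting
#' [stats::SSlogis()] parameterisation, falling back to Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) from heuristic starts (ASYM from 1.05 max y,
#' XMID from the half-maximum crossing, scal from the 25-75 percent rise
#' interval). Monotone non-saturating series (fitted asymptote far above the
#' observed maximum) are flagged non-converged and should be excluded from
#' species means.
#'
#' @param day Numeric vector of days since treatment start (strictly
#'   increasing, >= 4 observations).
#' @param length_mm Leaf lengths (mm, >= 0).
#' @return Class `"growth_fit"`: `ASYM` (mm), `XMID` (days), `scal` (days),
#'   `MGR` (= 1/scal, per day), `negXMID`, `resid_sd`, `converged`.
#' @export
fit_logistic <- function(day, length_mm) {
  if (length(day) != length(length_mm)) stop("day and length differ in length")
  ok <- is.finite(day) & is.finite(length_mm)
  day <- day[ok]; length_mm <- length_mm[ok]
  if (length(day) < 4L) stop("need at least 4 observations")
  if (is.unsorted(day, strictly = FALSE)) stop("days must be increasing")
  if (anyDuplicated(day))
    warning("duplicate observation days; duplicated points shift the fit")
  if (any(length_mm < 0)) stop("leaf lengths must be non-negative")

  df <- data.frame(t = day, y = length_mm)
  fit <- tryCatch(
    stats::nls(y ~ stats::SSlogis(t, Asym, xmid, scal), data = df),
    error = function(e) NULL)
  if (is.null(fit)) {
    ymax <- max(df$y)
    xmid0 <- df$t[which(df$y >= ymax / 2)[1L]]
    q <- try(c(df$t[which(df$y >= 0.25 * ymax)[1L]],
               df$t[which(df$y >= 0.75 * ymax)[1L]]), silent = TRUE)
    scal0 <- if (!inherits(q, "try-error") && !anyNA(q) && diff(q) > 0)
      diff(q) / 2.2 else diff(range(df$t)) / 4  # logistic 25-75% rise = 2.2 scal
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ Asym / (1 + exp((xmid - t) / scal)), data = df,
                        start = list(Asym = 1.05 * ymax, xmid = xmid0,
                                     scal = max(scal0, 1e-3)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    return(structure(list(ASYM = NA_real_, XMID = NA_real_, scal = NA_real_,
                          MGR = NA_real_, negXMID = NA_real_,
                          resid_sd = NA_real_, converged = FALSE),
                     class = "growth_fit"))
  }
  cf <- stats::coef(fit)
  # the asymptote is identified only if the plateau was observed: require
  # the fitted curve to reach 85% of ASYM by the last day, and the fitted
  # asymptote not to be a wild extrapolation of the data range
  y_last <- cf[["Asym"]] / (1 + exp((cf[["xmid"]] - max(df$t)) / cf[["scal"]]))
  converged <- is.finite(cf[["Asym"]]) && cf[["Asym"]] > 0 &&
    cf[["scal"]] > 0 && cf[["Asym"]] <= 3 * max(df$y) &&
    y_last >= 0.85 * cf[["Asym"]]
  structure(list(ASYM = cf[["Asym"]], XMID = cf[["xmid"]],
                 scal = cf[["scal"]], MGR = 1 / cf[["scal"]],
                 negXMID = -cf[["xmid"]],
                 resid_sd = stats::sd(stats::residuals(fit)),
                 converged = converged),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat("Logistic growth fit: ASYM = ", signif(x$ASYM, digits),
      " mm, XMID = ", signif(x$XMID, digits), " d, scal = ",
      signif(x$scal, digits), " d (MGR = ", signif(x$MGR, digits),
      "/d)", if (!x$converged) "  [not converged]", "\n", sep = "")
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(ASYM = object$ASYM, XMID = object$XMID, scal = object$scal,
    MGR = object$MGR, negXMID = object$negXMID)
}

#' Initial growth rate
#'
#' Ordinary least-squares slope of leaf length on day over the first
#' `window_days` days of treatment (default 7).
#'
#' @inheritParams fit_logistic
#' @param window_days Window width in days.
#' @return IGR in mm/day, or `NA` with fewer than 2 points in the window.
#' @export
initial_growth_rate <- function(day, length_mm, window_days = 7) {
  sel <- is.finite(day) & is.finite(length_mm) & day <= window_days
  if (sum(sel) < 2L) return(NA_real_)
  unname(stats::coef(stats::lm(length_mm[sel] ~ day[sel]))[2L])
}

#' Sign convention for the growth midpoint
#'
#' Smaller XMID means faster progression to mid-size, so XMID is negated to
#' represent progression of growth.
#'
#' @param xmid Time to half asymptotic size (days).
#' @export
negate_xmid <- function(xmid) -xmid

#' Stress tolerance of a growth parameter
#'
#' Relative change under stress: (stress - mild) / mild. Undefined (NA, with
#' a warning) when the mild estimate is zero.
#'
#' @param stress_estimate,mild_estimate Trait estimates under the stress and
#'   mild treatments.
#' @export
tolerance <- function(stress_estimate, mild_estimate) {
  out <- (stress_estimate - mild_estimate) / mild_estimate
  zero <- !is.na(mild_estimate) & mild_estimate == 0
  if (any(zero)) {
    warning("tolerance undefined where the mild estimate is zero")
    out[zero] <- NA_real_
  }
  out
}

#' Aggregate individual records to species means with measurement error
#'
#' Hierarchical averaging: replicate measures to plant means, plant means to
#' species x treatment x sowing-round means, and rounds to species x
#' treatment means. The standard error attached for the evolutionary models
#' is the SD across round means divided by sqrt(number of rounds); species
#' observed in a single round get the trait's median SE within treatment
#' imputed and are flagged.
#'
#' @param records data.frame with columns `species`, `treatment`, `round`,
#'   `plant`, `value` (one row per measurement; replicate measures of a
#'   plant share its `plant` id).
#' @return data.frame: `species`, `treatment`, `mean`, `se`, `n_rounds`,
#'   `se_imputed`.
#' @export
aggregate_species_means <- function(records) {
  req <- c("species", "treatment", "round", "plant", "value")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  records <- records[is.finite(records$value), , drop = FALSE]
  plant <- stats::aggregate(value ~ species + treatment + round + plant,
                            records, mean)
  round_m <- stats::aggregate(value ~ species + treatment + round, plant, mean)
  agg <- stats::aggregate(value ~ species + treatment, round_m,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  out <- data.frame(species = agg$species, treatment = agg$treatment,
                    mean = agg$value[, "mean"],
                    se = agg$value[, "sd"] / sqrt(agg$value[, "n"]),
                    n_rounds = as.integer(agg$value[, "n"]),
                    se_imputed = FALSE, stringsAsFactors = FALSE)
  single <- out$n_rounds < 2L
  if (any(single)) {
    for (tr in unique(out$treatment[single])) {
      med <- stats::median(out$se[out$treatment == tr & !single], na.rm = TRUE)
      idx <- single & out$treatment == tr
      out$se[idx] <- if (is.finite(med)) med else 0
      out$se_imputed[idx] <- TRUE
    }
  }
  rownames(out) <- NULL
  out
}
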