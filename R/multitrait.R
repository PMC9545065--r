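## Multivariate trade-off screening on the species x (trait, treatment)
## matrix: selective log10 + z-score standardization, iterative VIF pruning,
## discriminant analysis of principal components (DAPC) with stratified
## cross-validated PC retention, contribution-quantile trait selection, and
## pairwise Pearson correlations.

#' Standardize a trait matrix
#'
#' Applies log10 to the named columns (shifting by `1 - min` with a warning
#' if non-positive values occur) and then centers every column to mean zero
#' and scales to unit sample (n-1) standard deviation.
#'
#' @param x Numeric matrix or data.frame, species in rows, traits in columns.
#' @param log10_columns Character vector of columns to log10-transform.
#' @return Standardized numeric matrix.
#' @export
standardize_traits <- function(x, log10_columns = character(0)) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  bad <- setdiff(log10_columns, colnames(x))
  if (length(bad)) stop("unknown log10 columns: ", paste(bad, collapse = ", "))
  for (j in log10_columns) {
    v <- x[, j]
    if (any(v <= 0, na.rm = TRUE)) {
      off <- 1 - min(v, na.rm = TRUE)
      warning("column ", j, " shifted by ", signif(off, 4),
              " before log10 (non-positive values)")
      v <- v + off
    }
    x[, j] <- log10(v)
  }
  sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
  zero <- !is.finite(sds) | sds == 0
  if (any(zero))
    stop("zero-variance column(s): ", paste(colnames(x)[zero], collapse = ", "))
  scale(x)[, , drop = FALSE]
}

#' Iterative variance-inflation-factor pruning
#'
#' Repeatedly regresses each column on all others, computes
#' \eqn{VIF_j = 1/(1 - R^2_j)}, and drops the maximum-VIF column while the
#' maximum exceeds the threshold. Perfectly collinear columns (R^2 = 1) have
#' infinite VIF and are dropped first; ties go to the earlier column.
#'
#' @param x Numeric matrix (complete rows are used).
#' @param threshold VIF threshold (default 10).
#' @return List: `matrix` (pruned), `dropped` (column names in drop order),
#'   `vif` (final VIFs).
#' @export
vif_prune <- function(x, threshold = 10) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  dropped <- character(0)
  vifs_of <- function(m) {
    vapply(seq_len(ncol(m)), function(j) {
      # collinear probes trigger harmless perfect-fit warnings in summary.lm
      r2 <- tryCatch(
        suppressWarnings(
          summary(stats::lm(m[, j] ~ m[, -j, drop = FALSE]))$r.squared),
        error = function(e) 1)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  while (ncol(x) > 1L) {
    v <- vifs_of(x)
    if (max(v) <= threshold) break
    j <- which.max(v)          # ties and Inf resolve to the first column
    dropped <- c(dropped, colnames(x)[j])
    x <- x[, -j, drop = FALSE]
  }
  list(matrix = x, dropped = dropped,
       vif = stats::setNames(if (ncol(x) > 1L) vifs_of(x) else 1,
                             colnames(x)))
}

#' Discriminant analysis of principal components (two groups)
#'
#' PCA of the standardized matrix, retention of `n_pcs` score columns, and a
#' two-group linear discriminant on the scores. The discriminant vector is
#' mapped back to variable space through the PCA rotation; per-variable
#' contributions are its squared entries normalized to sum 1. Species with
#' missing values are excluded (counted in the result).
#'
#' @param x Standardized trait matrix, species in rows.
#' @param groups Factor/character of group labels (`low`/`high`), one per row.
#' @param n_pcs Number of principal components to retain (<= rank of `x`).
#' @return Class `"dapc_fit"`: `contributions`, `accuracy`, `posterior`,
#'   `assigned`, `n_pcs`, `loadings` (variable-space discriminant axis).
#' @export
dapc_fit <- function(x, groups, n_pcs) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  keep <- stats::complete.cases(x)
  n_excluded <- sum(!keep)
  x <- x[keep, , drop = FALSE]; groups <- droplevels(groups[keep])
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pca$sdev > 1e-10 * pca$sdev[1L])
  if (n_pcs > rank)
    stop("n_pcs (", n_pcs, ") exceeds the matrix rank (", rank, ")")
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  ld <- MASS::lda(scores, grouping = groups)
  pred <- stats::predict(ld)
  axis <- drop(pca$rotation[, seq_len(n_pcs), drop = FALSE] %*% ld$scaling[, 1L])
  contrib <- axis^2 / sum(axis^2)
  structure(list(contributions = contrib, loadings = axis,
                 accuracy = mean(pred$class == groups),
                 posterior = pred$posterior, assigned = pred$class,
                 groups = groups, n_pcs = n_pcs, n_excluded = n_excluded,
                 pca = pca, lda = ld),
            class = "dapc_fit")
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat("DAPC: ", x$n_pcs, " PCs retained, assignment accuracy ",
      round(100 * x$accuracy, 1), "%",
      if (x$n_excluded) paste0(" (", x$n_excluded, " species excluded)"),
      "\n", sep = "")
  top <- sort(x$contributions, decreasing = TRUE)
  print(signif(utils::head(top, 5L), 3))
  invisible(x)
}

#' Cross-validated choice of retained principal components
#'
#' For each candidate PC count, repeats a stratified holdout (default
#' 10 percent per group): PCA and LDA are trained on the training split and
#' holdout species are assigned. The optimum minimizes the mean squared
#' assignment error (1 - success)^2; ties break to the highest mean success,
#' then to fewer PCs.
#'
#' @inheritParams dapc_fit
#' @param grid Integer vector of candidate PC counts.
#' @param reps Holdout repetitions per grid level (default 1000; the full
#'   analysis uses more).
#' @param holdout_fraction Fraction held out per group (default 0.1).
#' @param seed Optional integer seed.
#' @return List: `n_pcs` (optimum), `table` (per-level mean success / MSE).
#' @export
xval_pc_retention <- function(x, groups, grid, reps = 1000L,
                              holdout_fraction = 0.1, seed = NULL) {
  if (!length(grid)) stop("empty PC grid")
  if (reps < 1L) stop("reps must be >= 1")
  x <- as.matrix(x)
  groups <- factor(groups)
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]; groups <- droplevels(groups[keep])
  if (any(table(groups) < 2L)) stop("each group needs at least 2 species")
  if (!is.null(seed)) set.seed(seed)
  idx_by_g <- split(seq_len(nrow(x)), groups)
  res <- lapply(grid, function(npc) {
    succ <- vapply(seq_len(reps), function(r) {
      hold <- unlist(lapply(idx_by_g, function(ix)
        sample(ix, max(1L, round(holdout_fraction * length(ix))))))
      tr_x <- x[-hold, , drop = FALSE]; tr_g <- groups[-hold]
      if (nlevels(droplevels(tr_g)) < 2L) return(NA_real_)
      pca <- stats::prcomp(tr_x, center = TRUE, scale. = FALSE)
      npc_eff <- min(npc, sum(pca$sdev > 1e-10 * pca$sdev[1L]))
      sc_tr <- pca$x[, seq_len(npc_eff), drop = FALSE]
      ld <- tryCatch(MASS::lda(sc_tr, grouping = droplevels(tr_g)),
                     error = function(e) NULL)
      if (is.null(ld)) return(NA_real_)
      sc_ho <- scale(x[hold, , drop = FALSE], center = pca$center,
                     scale = FALSE) %*% pca$rotation[, seq_len(npc_eff),
                                                     drop = FALSE]
      mean(stats::predict(ld, sc_ho)$class == groups[hold])
    }, 0)
    succ <- succ[is.finite(succ)]
    c(success = mean(succ), mse = mean((1 - succ)^2))
  })
  tab <- data.frame(n_pcs = grid, do.call(rbind, res))
  ord <- order(tab$mse, -tab$success, tab$n_pcs)
  list(n_pcs = tab$n_pcs[ord[1L]], table = tab)
}

#' Select discriminating traits by contribution quantile
#'
#' Returns the variables whose DAPC contribution exceeds the empirical
#' quantile (default the third quartile) of all contributions on the axis.
#'
#' @param fit A `"dapc_fit"` object.
#' @param quantile Probability (default 0.75).
#' @return Character vector of variable names.
#' @export
select_discriminating <- function(fit, quantile = 0.75) {
  q <- stats::quantile(fit$contributions, quantile)
  names(fit$contributions)[fit$contributions > q]
}

#' Pairwise Pearson correlations with significance stars
#'
#' Pairwise-complete Pearson r; two-sided p from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}. Cells with fewer than 3 complete pairs
#' are `NA`. Stars: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param x Numeric matrix, variables in columns.
#' @return Class `"cor_table"`: matrices `r`, `p`, `n`, `stars`.
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  p0 <- ncol(x)
  r <- p <- matrix(NA_real_, p0, p0, dimnames = list(colnames(x), colnames(x)))
  n <- matrix(0L, p0, p0, dimnames = dimnames(r))
  for (i in seq_len(p0)) for (j in i:p0) {
    ok <- stats::complete.cases(x[, c(i, j)])
    nij <- sum(ok)
    n[i, j] <- n[j, i] <- nij
    if (nij < 3L) next
    rij <- stats::cor(x[ok, i], x[ok, j])
    r[i, j] <- r[j, i] <- rij
    pij <- if (i == j || abs(rij) >= 1) 0 else {
      tt <- rij * sqrt((nij - 2) / (1 - rij^2))
      2 * stats::pt(-abs(tt), nij - 2)
    }
    p[i, j] <- p[j, i] <- pij
  }
  stars <- matrix("", p0, p0, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  diag(stars) <- ""
  structure(list(r = r, p = p, n = n, stars = stars), class = "cor_table")
}

#' @export
print.cor_table <- function(x, digits = 2, ...) {
  cat("Pairwise Pearson correlations (", ncol(x$r), " variables)\n", sep = "")
  m <- matrix(paste0(format(round(x$r, digits)), x$stars),
              nrow(x$r), dimnames = dimnames(x$r))
  print(m, quote = FALSE)
  invisible(x)
}
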