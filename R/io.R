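## Thin tabular ingest helpers for the package's external formats. All are
## plain TSV with a header row.

#' Read the package's tabular input formats
#'
#' `read_species_table()` expects columns `species` and `median_elevation_m`;
#' `read_trait_table()` expects `species`, `trait`, `treatment`, `mean`,
#' `se`, `n_rounds`; `read_individual_table()` expects the long individual
#' record format (`plant`, `species`, `population`, `line`, `block`,
#' `treatment`, `round`, `day`, `leaf_length_mm`). Column presence is
#' validated; resistance-style proportion columns (names starting `RES`)
#' must lie in \[0, 1\].
#'
#' @param file Path to a tab-separated file with a header.
#' @return A data.frame.
#' @export
read_species_table <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  need_cols(d, c("species", "median_elevation_m"), file)
  if (anyDuplicated(d$species))
    stop("duplicate species in ", file)
  d
}

#' @rdname read_species_table
#' @export
read_trait_table <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  need_cols(d, c("species", "trait", "treatment", "mean"), file)
  if (!"se" %in% names(d)) d$se <- NA_real_
  if (any(d$se < 0, na.rm = TRUE)) stop("negative SEs in ", file)
  res <- grep("^RES", d$trait)
  if (length(res) && any(d$mean[res] < 0 | d$mean[res] > 1, na.rm = TRUE))
    stop("resistance values outside [0, 1] in ", file)
  d
}

#' @rdname read_species_table
#' @export
read_individual_table <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  need_cols(d, c("plant", "species", "treatment", "round", "day",
                 "leaf_length_mm"), file)
  if (any(d$leaf_length_mm < 0, na.rm = TRUE))
    stop("negative leaf lengths in ", file)
  d
}

need_cols <- function(d, cols, file) {
  miss <- setdiff(cols, names(d))
  if (length(miss))
    stop(file, " lacks required columns: ", paste(miss, collapse = ", "))
  invisible(d)
}
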