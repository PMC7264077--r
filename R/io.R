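# Delimited-text exchange formats: the band-power CSV (rows = subjects,
# columns = s<idx>_<bandname>), the cohort CSV, and the PLS result directory.

#' Write a band-power matrix to CSV
#'
#' @param power A [band_power_matrix()].
#' @param path Output CSV path.
#' @param subject_ids Optional subject identifiers for the first column.
#' @export
write_band_power_csv <- function(power, path, subject_ids = NULL) {
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub%03d", seq_len(nrow(power)))
  df <- data.frame(subject_id = subject_ids, unclass(power),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a band-power matrix from CSV
#'
#' Reconstructs the source/band layout from the `s<idx>_<bandname>` column
#' headers; band edges are taken from `bands` (default canonical).
#'
#' @param path CSV path produced by [write_band_power_csv()].
#' @param bands Band definition data frame.
#' @return A [band_power_matrix()] with `rownames` set to the subject IDs.
#' @export
read_band_power_csv <- function(path, bands = canonical_bands()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df$subject_id
  m <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  parsed <- regmatches(colnames(m), regexec("^s([0-9]+)_(.+)$", colnames(m)))
  if (any(lengths(parsed) != 3L))
    stop("column headers must follow s<idx>_<bandname>")
  n_sources <- max(as.integer(vapply(parsed, `[`, "", 2L)))
  expected <- feature_names(n_sources, bands)
  if (!identical(colnames(m), expected))
    stop("column order does not match the source-major s<idx>_<band> layout")
  out <- band_power_matrix(m, n_sources = n_sources, bands = bands)
  rownames(out) <- ids
  out
}

#' Serialize a PLS result as a directory of CSV files
#'
#' Writes `singular_values.csv`, `p_values.csv`, `contrasts.csv` (with 95%
#' CI columns when available), `saliences.csv`, `bootstrap_ratios.csv` and
#' `brain_scores.csv` plus a JSON manifest of the run options.
#'
#' @param result A [run_pls()] result.
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest.
#' @return The directory path, invisibly.
#' @export
write_pls_result <- function(result, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) utils::write.csv(df, file.path(dir, file),
                                           row.names = FALSE)
  k <- length(result$singular_values)
  w(data.frame(LV = seq_len(k), singular_value = result$singular_values),
    "singular_values.csv")
  if (!is.null(result$p_values))
    w(data.frame(LV = seq_len(k), p = result$p_values), "p_values.csv")
  cdf <- data.frame(element = rownames(result$contrasts),
                    result$contrasts, check.names = FALSE)
  if (!is.null(result$contrast_ci_lower)) {
    ci_lo <- result$contrast_ci_lower
    ci_hi <- result$contrast_ci_upper
    colnames(ci_lo) <- paste0(colnames(result$contrasts), "_ci_lower")
    colnames(ci_hi) <- paste0(colnames(result$contrasts), "_ci_upper")
    cdf <- cbind(cdf, ci_lo, ci_hi)
  }
  w(cdf, "contrasts.csv")
  w(data.frame(feature = rownames(result$saliences), result$saliences,
               check.names = FALSE), "saliences.csv")
  if (!is.null(result$bootstrap_ratios))
    w(data.frame(feature = rownames(result$bootstrap_ratios),
                 result$bootstrap_ratios, check.names = FALSE),
      "bootstrap_ratios.csv")
  if (!is.null(result$brain_scores))
    w(data.frame(subject = seq_len(nrow(result$brain_scores)),
                 result$brain_scores, check.names = FALSE),
      "brain_scores.csv")
  manifest <- list(type = result$type, n_perm = result$n_perm,
                   n_boot = result$n_boot, seed = seed,
                   n_features = nrow(result$saliences),
                   n_lv = k)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
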