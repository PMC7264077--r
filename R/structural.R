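# Structural variables and the thalamic-to-cortical volume composite.

#' Thalamic to cortical gray matter volume ratio
#'
#' The composite indexing thalamic mass relative to cortical mass: thalamic
#' volume divided by cortical gray matter volume. Scale-invariant (common
#' rescaling of both volumes leaves it unchanged), strictly increasing in TV
#' and strictly decreasing in CGV.
#'
#' @param TV Thalamic volume(s), mm^3 (hemispheric mean).
#' @param CGV Cortical gray matter volume(s), mm^3. Must be positive.
#' @return `TV / CGV`, dimensionless.
#' @export
#' @examples
#' tv_cgv_ratio(6951, 536606)
tv_cgv_ratio <- function(TV, CGV) {
  if (any(!is.na(CGV) & CGV <= 0))
    stop("CGV must be positive to form the TV-CGV ratio")
  TV / CGV
}

.outcome_columns <- function() .default_outcome_table()$name
.structural_columns <- function() c("TV", "CGV", "ICV", "TI", "CGI", "CWI")
.neonatal_columns <- function() c("GA", "sex", "infection", "SNAP", "morphine", "pain")

#' Validate a cohort table and report per-analysis availability
#'
#' Checks the column dictionary of a cohort table, rejects duplicate subject
#' identifiers, flags out-of-range values (gestational age outside (22, 43)
#' weeks, non-positive volumes, volume ordering TV < CGV < ICV, normalized
#' intensities outside 0-255), and reports complete-case counts for each of
#' the four analysis families (spectral, neurocognitive, structural,
#' neonatal).
#'
#' @param table Data frame with at least `subject_id` and `group` columns.
#' @return A `cohort_validation` list: `table` (unchanged), `availability`
#'   (named counts) and `flags` (data frame of value violations, possibly
#'   empty). Validation is idempotent.
#' @export
validate_cohort_table <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L) stop("cohort table is empty")
  if (!all(c("subject_id", "group") %in% names(table)))
    stop("cohort table must have `subject_id` and `group` columns")
  if (anyDuplicated(table$subject_id))
    stop("duplicate subject IDs: ",
         paste(unique(table$subject_id[duplicated(table$subject_id)]),
               collapse = ", "))
  flags <- data.frame(subject_id = character(0), column = character(0),
                      value = numeric(0), rule = character(0),
                      stringsAsFactors = FALSE)
  flag <- function(bad, column, rule) {
    bad <- which(bad)
    if (length(bad))
      flags <<- rbind(flags, data.frame(
        subject_id = table$subject_id[bad], column = column,
        value = table[[column]][bad], rule = rule,
        stringsAsFactors = FALSE))
  }
  if ("GA" %in% names(table))
    flag(!is.na(table$GA) & (table$GA <= 22 | table$GA >= 43),
         "GA", "GA in (22, 43) weeks")
  for (v in c("TV", "CGV", "ICV"))
    if (v %in% names(table))
      flag(!is.na(table[[v]]) & table[[v]] <= 0, v, "volume > 0")
  if (all(c("TV", "CGV", "ICV") %in% names(table))) {
    ok <- with(table, !is.na(TV) & !is.na(CGV) & !is.na(ICV))
    flag(ok & !(table$TV < table$CGV & table$CGV < table$ICV),
         "TV", "TV < CGV < ICV")
  }
  for (v in c("TI", "CGI", "CWI"))
    if (v %in% names(table))
      flag(!is.na(table[[v]]) & (table[[v]] < 0 | table[[v]] > 255),
           v, "normalized intensity in [0, 255]")
  complete_on <- function(cols) {
    cols <- intersect(cols, names(table))
    if (!length(cols)) return(0L)
    sum(stats::complete.cases(table[, cols, drop = FALSE]))
  }
  availability <- c(
    spectral = nrow(table),
    neurocognitive = complete_on(.outcome_columns()),
    structural = complete_on(.structural_columns()),
    neonatal = complete_on(.neonatal_columns())
  )
  structure(list(table = table, availability = availability, flags = flags),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("cohort_validation:", nrow(x$table), "subjects\n")
  cat("complete cases per analysis family:\n")
  print(x$availability)
  if (nrow(x$flags)) {
    cat(nrow(x$flags), "value flag(s):\n")
    print(utils::head(x$flags, 10L))
  } else cat("no value flags\n")
  invisible(x)
}
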