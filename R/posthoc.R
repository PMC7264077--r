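# Post-hoc analyses around the PLS results: salience-map correlations,
# tail-power associations, brain-score vs volume correlations, and the
# neonatal-predictor regressions.

#' Correlate two bootstrap-ratio maps
#'
#' Pearson correlation over all source-by-band features of two aligned
#' z-score maps (e.g. from two different PLS analyses on the same grid).
#'
#' @param z1,z2 Sources-by-bands matrices (see [zmap()]) with identical
#'   layout.
#' @return A single Pearson correlation.
#' @export
correlate_zmaps <- function(z1, z2) {
  z1 <- unclass(as.matrix(z1)); z2 <- unclass(as.matrix(z2))
  if (!identical(dim(z1), dim(z2)))
    stop("z maps have different dimensions")
  if (!is.null(colnames(z1)) && !is.null(colnames(z2)) &&
      !identical(colnames(z1), colnames(z2)))
    stop("z maps have different band layouts")
  if (!all(is.finite(z1)) || !all(is.finite(z2))) stop("z maps must be finite")
  stats::cor(as.vector(z1), as.vector(z2))
}

# Adjusted Fisher-Pearson (bias-corrected) sample skewness.
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) stop("skewness needs at least 3 values")
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / n)
  g1 <- sum((x - m)^3) / n / s^3
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

.cor_with_p <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 4L) return(c(n = n, r = NA_real_, p = NA_real_))
  ct <- stats::cor.test(x[ok], y[ok])
  c(n = n, r = unname(ct$estimate), p = ct$p.value)
}

#' Tail-power association with a covariate
#'
#' For each frequency band, selects the locations in the skewed tail of the
#' band's z-scores (the most-negative tail when the sample skewness is
#' negative, the most-positive tail otherwise), averages each subject's
#' relative power over the selected locations, and correlates the averages
#' with a covariate per group and pooled over all subjects. Ties at the
#' cutoff are broken by ascending source index, so the selection is a
#' deterministic function of the map.
#'
#' @param z Sources-by-bands z-score map.
#' @param power A [band_power_matrix()] on the same source/band layout.
#' @param covariate Per-subject numeric covariate (e.g. the TV-CGV ratio);
#'   subjects with `NA` are dropped from correlations.
#' @param groups Optional factor of group labels for per-group correlations.
#' @param fraction Tail fraction in (0, 0.5); `ceiling(fraction * n_sources)`
#'   locations are selected per band (default 0.025).
#' @return List with one element per band: `band`, `skewness`, `tail`
#'   (`"negative"`/`"positive"`), `selected_sources`, `subject_mean_power`
#'   and a `correlations` data frame (rows per group plus `"all"`).
#' @export
tail_power_association <- function(z, power, covariate, groups = NULL,
                                   fraction = 0.025) {
  z <- unclass(as.matrix(z))
  if (fraction <= 0 || fraction >= 0.5) stop("`fraction` must be in (0, 0.5)")
  ns <- attr(power, "n_sources")
  bands <- attr(power, "bands")
  if (is.null(ns) || is.null(bands))
    stop("`power` must be a band_power_matrix with layout attributes")
  if (nrow(z) != ns || ncol(z) != nrow(bands))
    stop("z map layout does not match the power matrix")
  if (length(covariate) != nrow(power))
    stop("`covariate` must have one value per subject")
  nb <- nrow(bands)
  k <- as.integer(ceiling(fraction * ns))
  out <- vector("list", nb)
  names(out) <- bands$name
  for (b in seq_len(nb)) {
    zb <- z[, b]
    sk <- sample_skewness(zb)
    ord <- if (sk < 0) order(zb, seq_len(ns)) else order(-zb, seq_len(ns))
    sel <- sort(ord[seq_len(k)])
    cols <- (sel - 1L) * nb + b          # source-major feature layout
    mp <- rowMeans(power[, cols, drop = FALSE])
    rows <- list()
    if (!is.null(groups)) {
      groups <- as.factor(groups)
      for (lev in levels(groups)) {
        i <- groups == lev
        rows[[lev]] <- c(group = lev,
                         .cor_with_p(mp[i], covariate[i]))
      }
    }
    rows[["all"]] <- c(group = "all", .cor_with_p(mp, covariate))
    cor_df <- do.call(rbind, lapply(rows, function(r)
      data.frame(group = r[["group"]], n = as.integer(r[["n"]]),
                 r = as.numeric(r[["r"]]), p = as.numeric(r[["p"]]),
                 stringsAsFactors = FALSE)))
    rownames(cor_df) <- NULL
    out[[b]] <- list(band = bands$name[b], skewness = sk,
                     tail = if (sk < 0) "negative" else "positive",
                     selected_sources = sel,
                     subject_mean_power = mp,
                     correlations = cor_df)
  }
  out
}

#' Correlate brain scores with structural volumes
#'
#' Pearson correlation (two-sided p from the t transform) of per-subject
#' brain scores with each volume variable separately, over subjects with
#' structural data.
#'
#' @param scores Numeric vector of brain scores (one LV).
#' @param TV,CGV Volume vectors aligned with `scores`; `NA` rows dropped
#'   per variable.
#' @return Data frame with one row per volume variable: `variable`, `n`,
#'   `r`, `p`.
#' @export
correlate_scores_with_volumes <- function(scores, TV, CGV) {
  vols <- list(TV = TV, CGV = CGV)
  rows <- lapply(names(vols), function(v) {
    x <- vols[[v]]
    ok <- stats::complete.cases(scores, x)
    if (sum(ok) < 4L) stop("fewer than 4 complete cases for ", v)
    if (stats::sd(x[ok]) == 0) stop(v, " has zero variance")
    ct <- stats::cor.test(scores[ok], x[ok])
    data.frame(variable = v, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Neonatal-predictor regression of thalamic structure
#'
#' Ordinary least squares with intercept of a thalamic outcome (normalized
#' thalamic intensity `TI`, or the TV-CGV ratio) on the seven neonatal
#' predictors: gestational age, sex, infection, day-1 illness severity
#' (SNAP), log cumulative morphine dose, log count of skin-breaking
#' procedures, and the sex-by-GA interaction. Complete cases only; with 37
#' complete cases the overall F statistic has (7, 29) degrees of freedom.
#'
#' @param cohort Cohort data frame with the neonatal columns and the outcome
#'   (the TV-CGV ratio is derived from `TV` and `CGV` when requested).
#' @param outcome `"TI"` or `"TV_CGV"`.
#' @return A `regression_result` list: `outcome`, `n`, `coefficients` (term,
#'   beta, p in the conventional reporting order), `F`, `df1`, `df2`,
#'   `r_squared`, and the underlying `lm` fit.
#' @export
neonatal_regression <- function(cohort, outcome = c("TI", "TV_CGV")) {
  outcome <- match.arg(outcome)
  need <- .neonatal_columns()
  if (!all(need %in% names(cohort)))
    stop("cohort lacks neonatal columns: ",
         paste(setdiff(need, names(cohort)), collapse = ", "))
  y <- if (outcome == "TI") cohort$TI else tv_cgv_ratio(cohort$TV, cohort$CGV)
  df <- data.frame(y = y, cohort[, need, drop = FALSE])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < 9L) stop("need at least 9 complete cases for 7 predictors")
  fit <- stats::lm(y ~ GA + sex + infection + SNAP + morphine + pain + sex:GA,
                   data = df)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: perfectly collinear predictors")
  sm <- summary(fit)
  ct <- sm$coefficients
  terms_order <- c("GA", "sex", "infection", "SNAP", "morphine", "pain", "GA:sex")
  coefs <- data.frame(
    term = terms_order,
    beta = ct[terms_order, "Estimate"],
    p = ct[terms_order, "Pr(>|t|)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  fstat <- sm$fstatistic
  structure(list(outcome = outcome, n = n, coefficients = coefs,
                 F = unname(fstat["value"]), df1 = unname(fstat["numdf"]),
                 df2 = unname(fstat["dendf"]), r_squared = sm$r.squared,
                 intercept = unname(ct["(Intercept)", "Estimate"]),
                 fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("regression_result: ", x$outcome, " ~ 7 neonatal predictors, n = ",
      x$n, "\n", sep = "")
  cat(sprintf("F(%d, %d) = %.3f, R^2 = %.3f\n", x$df1, x$df2, x$F, x$r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}
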