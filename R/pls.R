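# Mean-centered and behavioral Partial Least Squares.
#
# Both variants decompose a small cross-block matrix by SVD into latent
# variables (LV): a feature-side left singular vector (the salience), a
# singular value, and a group- or variable-side right singular vector (the
# contrast). Inference is non-parametric: permutation of group labels (or of
# behavioral rows) for LV significance, and within-group bootstrap
# resampling for feature reliability (bootstrap ratios, presented as
# z-scores) and contrast confidence intervals.

.check_groups <- function(X, groups) {
  groups <- as.factor(groups)
  if (length(groups) != nrow(X)) stop("`groups` length must match rows of X")
  cnt <- table(groups)
  if (length(cnt) < 2L) stop("mean-centered PLS needs at least 2 groups")
  if (any(cnt < 2L))
    stop("every group needs n >= 2 (offending: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "), ")")
  droplevels(groups)
}

# Group-means matrix (groups x features), rows in level order.
.group_means <- function(X, groups) {
  rowsum(X, groups, reorder = TRUE) / as.vector(table(groups))
}

# Column-center the group-means matrix. Unweighted: grand mean of group
# means (each group counts equally); weighted: overall subject mean.
.center_group_means <- function(M, X, weighted) {
  ctr <- if (weighted) colMeans(X) else colMeans(M)
  sweep(M, 2L, ctr)
}

# Sign convention: fix each LV so the largest-magnitude contrast element is
# positive (the decomposition is sign-arbitrary).
.fix_signs <- function(U, d, V) {
  for (j in seq_along(d)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  list(U = U, V = V)
}

.pls_point <- function(U, d, V, features, side_names, type) {
  fx <- .fix_signs(U, d, V)
  structure(list(
    singular_values = d,
    saliences = matrix(fx$U, ncol = length(d),
                       dimnames = list(features, paste0("LV", seq_along(d)))),
    contrasts = matrix(fx$V, ncol = length(d),
                       dimnames = list(side_names, paste0("LV", seq_along(d)))),
    type = type
  ), class = "pls_result")
}

#' Mean-centered PLS point estimates
#'
#' Builds the groups-by-features matrix of group means, centers each feature
#' by the grand mean of group means (each group weighted equally, so the
#' contrast is not dominated by the largest group; set `weighted = TRUE` to
#' center by the overall subject mean instead), and decomposes it by SVD.
#' At most `n_groups - 1` singular values are non-zero.
#'
#' @param X Subjects-by-features numeric matrix (e.g. a
#'   [band_power_matrix()]).
#' @param groups Factor of group labels, one per subject, each group n >= 2.
#' @param weighted Center by the group-size-weighted grand mean (default
#'   `FALSE`).
#' @return A `pls_result` with `singular_values`, `saliences` (features by
#'   LVs, unit-norm columns) and `contrasts` (groups by LVs, unit-norm
#'   columns).
#' @export
mean_centered_pls <- function(X, groups, weighted = FALSE) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values")
  groups <- .check_groups(X, groups)
  M <- .group_means(X, groups)
  Mc <- .center_group_means(M, X, weighted)
  sv <- svd(t(Mc))                    # features x groups
  .pls_point(sv$u, sv$d, sv$v, colnames(X), levels(groups), "mean_centered")
}

# Correlation matrix robust to zero-variance columns (bootstrap internals);
# zero-variance pairs contribute correlation 0.
.safe_cor <- function(X, Y) {
  sx <- apply(X, 2L, stats::sd)
  sy <- apply(Y, 2L, stats::sd)
  Xs <- scale(X, center = TRUE, scale = ifelse(sx > 0, sx, 1))
  Ys <- scale(Y, center = TRUE, scale = ifelse(sy > 0, sy, 1))
  Xs[, sx == 0] <- 0
  Ys[, sy == 0] <- 0
  crossprod(Xs, Ys) / (nrow(X) - 1L)
}

#' Behavioral PLS point estimates
#'
#' Decomposes the features-by-variables matrix of Pearson correlations
#' computed across all included subjects (subjects from all groups are
#' pooled). The variable-side singular vectors are the contrasts; rescaled
#' by their singular value they are interpretable as the correlation pattern
#' of the variables with the latent brain pattern.
#'
#' @param X Subjects-by-features numeric matrix.
#' @param Y Subjects-by-variables numeric matrix, rows aligned with `X`.
#' @return A `pls_result` with `singular_values`, `saliences` (features by
#'   LVs) and `contrasts` (variables by LVs).
#' @export
behavioral_pls <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("V", seq_len(ncol(Y)))
  if (nrow(X) != nrow(Y)) stop("X and Y must have aligned subject rows")
  if (anyNA(X) || anyNA(Y))
    stop("missing values must be removed (listwise) before behavioral PLS")
  sdx <- apply(X, 2L, stats::sd)
  if (any(sdx == 0))
    stop("constant feature(s): ",
         paste(utils::head(colnames(X)[sdx == 0], 5L), collapse = ", "))
  sdy <- apply(Y, 2L, stats::sd)
  if (any(sdy == 0))
    stop("constant variable(s): ",
         paste(colnames(Y)[sdy == 0], collapse = ", "))
  R <- stats::cor(X, Y)
  sv <- svd(R)
  .pls_point(sv$u, sv$d, sv$v, colnames(X), colnames(Y), "behavioral")
}

# Fast singular values only (permutation internals).
.mc_singvals <- function(X, groups, weighted) {
  M <- .group_means(X, groups)
  Mc <- .center_group_means(M, X, weighted)
  svd(Mc, nu = 0, nv = 0)$d
}

.beh_singvals <- function(X, Y) {
  svd(.safe_cor(X, Y), nu = 0, nv = 0)$d
}

#' Permutation test on PLS singular values
#'
#' Significance of each LV by resampling without replacement: for
#' mean-centered PLS the subjects' group assignment is permuted; for
#' behavioral PLS the subject rows of `Y` are permuted against `X`. The full
#' decomposition is recomputed for every permutation, and the p-value of LV
#' k is the smoothed exceedance proportion
#' `(#\{s_perm(k) >= s_obs(k)\} + 1) / (n_perm + 1)`.
#'
#' @param X Subjects-by-features matrix.
#' @param groups Group factor (mean-centered PLS) or `NULL`.
#' @param Y Behavior matrix (behavioral PLS) or `NULL`. Exactly one of
#'   `groups`/`Y` selects the analysis; for behavioral PLS `groups` is
#'   ignored here.
#' @param n_perm Number of permutations (>= 100; fewer triggers a warning).
#' @param seed Optional integer seed.
#' @param weighted Mean-centering variant (see [mean_centered_pls()]).
#' @return List with `p_values` (one per LV) and `perm_singular_values`
#'   (n_perm by LVs).
#' @export
permutation_test <- function(X, groups = NULL, Y = NULL, n_perm = 500,
                             seed = NULL, weighted = FALSE) {
  X <- as.matrix(X)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value grid")
  if (!is.null(seed)) set.seed(seed)
  behavioral <- !is.null(Y)
  if (behavioral) {
    Y <- as.matrix(Y)
    s_obs <- svd(stats::cor(X, Y), nu = 0, nv = 0)$d
  } else {
    groups <- .check_groups(X, groups)
    s_obs <- .mc_singvals(X, groups, weighted)
  }
  k <- length(s_obs)
  perm <- matrix(0, n_perm, k)
  n <- nrow(X)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n)
    perm[p, ] <- if (behavioral) .beh_singvals(X, Y[idx, , drop = FALSE])
                 else .mc_singvals(X, groups[idx], weighted)
  }
  exceed <- colSums(sweep(perm, 2L, s_obs, ">=") * 1)
  list(p_values = (exceed + 1) / (n_perm + 1),
       perm_singular_values = perm,
       observed_singular_values = s_obs)
}

# One within-group bootstrap index vector; redraw (up to max_redraw) any
# resample that collapses a group to a single unique subject.
.boot_indices <- function(groups, max_redraw = 100L) {
  idx <- integer(length(groups))
  for (lev in levels(groups)) {
    g <- which(groups == lev)
    for (try in seq_len(max_redraw + 1L)) {
      draw <- sample(g, length(g), replace = TRUE)
      if (length(unique(draw)) > 1L) break
      if (try > max_redraw)
        stop("bootstrap resample of group ", lev,
             " collapsed to one unique subject ", max_redraw, " times")
    }
    idx[g] <- draw
  }
  idx
}

#' Bootstrap reliability of PLS saliences and contrasts
#'
#' Resamples subjects with replacement within each group, recomputes the
#' decomposition, sign-aligns each resampled LV to the original (flipping
#' when the dot product of the resampled and original saliences is
#' negative), and accumulates. The bootstrap ratio of a feature is its
#' original salience divided by the bootstrap standard error of the aligned
#' saliences (a z-score of feature reliability; defined as 0 where the SE
#' vanishes). Contrast confidence intervals are the 2.5/97.5 percentiles of
#' the aligned bootstrap contrast elements; intervals excluding 0 are read
#' as significant.
#'
#' @param X Subjects-by-features matrix.
#' @param groups Group factor (resampling strata). For behavioral PLS with a
#'   single undivided sample, pass a constant factor.
#' @param Y Behavior matrix for behavioral PLS, or `NULL` for mean-centered.
#' @param n_boot Number of bootstrap resamples (>= 100 recommended).
#' @param seed Optional integer seed.
#' @param weighted Mean-centering variant.
#' @return List with `bootstrap_ratios` (features by LVs), `salience_se`,
#'   `contrast_ci_lower`, `contrast_ci_upper` and the original point
#'   estimates.
#' @export
bootstrap_inference <- function(X, groups, Y = NULL, n_boot = 500,
                                seed = NULL, weighted = FALSE) {
  X <- as.matrix(X)
  if (n_boot < 100) warning("n_boot < 100 gives unstable standard errors")
  if (!is.null(seed)) set.seed(seed)
  behavioral <- !is.null(Y)
  groups <- as.factor(groups)
  if (any(table(groups) < 2L)) stop("every group needs n >= 2 for bootstrapping")
  base <- if (behavioral) behavioral_pls(X, Y)
          else mean_centered_pls(X, groups, weighted)
  U0 <- base$saliences
  k <- length(base$singular_values)
  sum_u <- matrix(0, nrow(U0), k)
  sumsq_u <- matrix(0, nrow(U0), k)
  vdraws <- array(0, dim = c(nrow(base$contrasts), k, n_boot))
  for (b in seq_len(n_boot)) {
    idx <- .boot_indices(groups)
    Xb <- X[idx, , drop = FALSE]
    if (behavioral) {
      Rb <- .safe_cor(Xb, Y[idx, , drop = FALSE])
      sv <- svd(Rb)
    } else {
      M <- .group_means(Xb, groups)           # strata keep their labels
      Mc <- .center_group_means(M, Xb, weighted)
      sv <- svd(t(Mc))
    }
    Ub <- sv$u[, seq_len(k), drop = FALSE]
    Vb <- sv$v[, seq_len(k), drop = FALSE]
    flip <- colSums(Ub * U0) < 0
    Ub[, flip] <- -Ub[, flip, drop = FALSE]
    Vb[, flip] <- -Vb[, flip, drop = FALSE]
    # accumulate deviations from the original salience: numerically exact
    # when resamples are degenerate (identical to the original)
    D <- Ub - U0
    sum_u <- sum_u + D
    sumsq_u <- sumsq_u + D^2
    vdraws[, , b] <- Vb
  }
  se <- sqrt(pmax((sumsq_u - sum_u^2 / n_boot) / (n_boot - 1), 0))
  bsr <- ifelse(se < 1e-12, 0, U0 / se)
  dimnames(bsr) <- dimnames(U0)
  ci <- apply(vdraws, c(1L, 2L), stats::quantile, probs = c(0.025, 0.975))
  lower <- matrix(ci[1L, , ], ncol = k, dimnames = dimnames(base$contrasts))
  upper <- matrix(ci[2L, , ], ncol = k, dimnames = dimnames(base$contrasts))
  list(bootstrap_ratios = bsr, salience_se = se,
       contrast_ci_lower = lower, contrast_ci_upper = upper,
       point = base)
}

#' Brain scores
#'
#' Per-subject expression of an LV's pattern: the dot product of the
#' subjects-by-features matrix with each salience vector.
#'
#' @param X Subjects-by-features matrix.
#' @param saliences Features-by-LVs salience matrix.
#' @return Subjects-by-LVs matrix of scores.
#' @export
brain_scores <- function(X, saliences) {
  X <- as.matrix(X); saliences <- as.matrix(saliences)
  if (ncol(X) != nrow(saliences))
    stop("feature dimensions of X (", ncol(X), ") and saliences (",
         nrow(saliences), ") do not match")
  scores <- X %*% saliences
  colnames(scores) <- colnames(saliences)
  scores
}

#' Run a full PLS analysis with inference
#'
#' Convenience wrapper combining the point decomposition, the permutation
#' test, the within-group bootstrap and the brain scores into a single
#' `pls_result`.
#'
#' @param X Subjects-by-features matrix.
#' @param groups Group factor; required for mean-centered PLS and used as
#'   bootstrap strata for behavioral PLS (a constant factor if no grouping).
#' @param Y Behavior matrix for behavioral PLS, or `NULL` for mean-centered.
#' @param n_perm,n_boot Resampling counts (defaults 500).
#' @param seed Optional integer seed driving both resampling schemes.
#' @param weighted Mean-centering variant.
#' @return A `pls_result` with point estimates, `p_values`,
#'   `bootstrap_ratios`, `contrast_ci_lower`/`upper` and `brain_scores`.
#' @export
run_pls <- function(X, groups = NULL, Y = NULL, n_perm = 500, n_boot = 500,
                    seed = NULL, weighted = FALSE) {
  X <- as.matrix(X)
  if (is.null(groups)) groups <- factor(rep("all", nrow(X)))
  groups <- as.factor(groups)
  if (!is.null(seed)) set.seed(seed)
  res <- if (is.null(Y)) mean_centered_pls(X, groups, weighted)
         else behavioral_pls(X, Y)
  pt <- permutation_test(X, groups = if (is.null(Y)) groups else NULL,
                         Y = Y, n_perm = n_perm, seed = NULL,
                         weighted = weighted)
  bi <- bootstrap_inference(X, groups, Y = Y, n_boot = n_boot, seed = NULL,
                            weighted = weighted)
  res$p_values <- pt$p_values
  res$perm_singular_values <- pt$perm_singular_values
  res$bootstrap_ratios <- bi$bootstrap_ratios
  res$salience_se <- bi$salience_se
  res$contrast_ci_lower <- bi$contrast_ci_lower
  res$contrast_ci_upper <- bi$contrast_ci_upper
  res$brain_scores <- brain_scores(X, res$saliences)
  res$n_perm <- n_perm
  res$n_boot <- n_boot
  res$groups <- groups
  if (inherits(X, "band_power_matrix") || !is.null(attr(X, "n_sources"))) {
    res$n_sources <- attr(X, "n_sources")
    res$bands <- attr(X, "bands")
  }
  res
}

#' @export
print.pls_result <- function(x, ...) {
  cat("pls_result (", x$type, "): ", nrow(x$saliences), " features, ",
      length(x$singular_values), " LV(s)\n", sep = "")
  df <- data.frame(singular_value = x$singular_values)
  if (!is.null(x$p_values)) df$p <- x$p_values
  print(df, ...)
  invisible(x)
}

#' Bootstrap-ratio salience map
#'
#' Reshapes one LV's bootstrap ratios into a sources-by-bands z-score map.
#'
#' @param result A [run_pls()] result carrying `bootstrap_ratios` and the
#'   source/band layout, or supply `n_sources`/`bands` explicitly.
#' @param lv Which latent variable (default 1).
#' @param n_sources,bands Feature layout overrides.
#' @return Sources-by-bands matrix of z-scores (class `zmap`).
#' @export
zmap <- function(result, lv = 1L, n_sources = result$n_sources,
                 bands = result$bands) {
  if (is.null(result$bootstrap_ratios))
    stop("result has no bootstrap ratios; run run_pls() or bootstrap_inference()")
  if (is.null(n_sources) || is.null(bands))
    stop("source/band layout unknown; pass n_sources and bands")
  v <- result$bootstrap_ratios[, lv]
  m <- matrix(v, nrow = n_sources, byrow = TRUE,
              dimnames = list(NULL, bands$name))
  structure(m, class = c("zmap", "matrix", "array"))
}
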