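# Independent oracles used across the suite. Each is written as a direct,
# naive computation so it shares no code path with the package internals.

# Dense SVD via the eigendecomposition of the Gram matrix (independent of
# base svd() as used inside the package).
oracle_svd <- function(M) {
  G <- t(M) %*% M
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  d <- sqrt(pmax(eg$values, 0))
  V <- eg$vectors
  U <- matrix(0, nrow(M), ncol(M))
  for (j in seq_along(d)) if (d[j] > 1e-12) U[, j] <- M %*% V[, j] / d[j]
  list(d = d, u = U, v = V)
}

# Group-means matrix by explicit loops.
oracle_group_means <- function(X, groups) {
  levs <- levels(as.factor(groups))
  M <- matrix(0, length(levs), ncol(X))
  for (i in seq_along(levs)) {
    rows <- which(groups == levs[i])
    for (j in seq_len(ncol(X))) M[i, j] <- mean(X[rows, j])
  }
  rownames(M) <- levs
  M
}

# Naive dot products.
oracle_brain_scores <- function(X, U) {
  S <- matrix(0, nrow(X), ncol(U))
  for (i in seq_len(nrow(X))) for (k in seq_len(ncol(U)))
    S[i, k] <- sum(X[i, ] * U[, k])
  S
}

# OLS by the normal equations.
oracle_ols <- function(X, y) {
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Welch-style band-power oracle: average raw periodograms (spec.pgram,
# untapered, undetrended) over epochs and integrate over [lo, hi).
oracle_band_power_psd <- function(x, fs, epoch_len, lo, hi) {
  n_ep <- floor(length(x) / epoch_len)
  psd_sum <- NULL
  for (e in seq_len(n_ep)) {
    seg <- x[((e - 1) * epoch_len + 1):(e * epoch_len)]
    sp <- stats::spec.pgram(stats::ts(seg, frequency = fs), taper = 0,
                            detrend = FALSE, fast = FALSE, plot = FALSE)
    psd_sum <- if (is.null(psd_sum)) sp$spec else psd_sum + sp$spec
  }
  freq <- sp$freq
  df <- freq[2] - freq[1]
  # spec.pgram spectra integrate to var/2 over positive freqs x2 convention
  sel <- freq >= lo & freq < hi
  2 * sum(psd_sum[sel] / n_ep) * df
}

# Independent re-implementation of the conducting-sphere dipole field,
# written from the component expressions rather than vector algebra.
oracle_sphere_field <- function(r0, q, r) {
  mu0 <- 4 * pi * 1e-7
  ax <- r[1] - r0[1]; ay <- r[2] - r0[2]; az <- r[3] - r0[3]
  a <- sqrt(ax^2 + ay^2 + az^2)
  rn <- sqrt(r[1]^2 + r[2]^2 + r[3]^2)
  r0dotr <- r0[1] * r[1] + r0[2] * r[2] + r0[3] * r[3]
  adotr <- ax * r[1] + ay * r[2] + az * r[3]
  F <- a * (rn * a + rn^2 - r0dotr)
  c1 <- a^2 / rn + adotr / a + 2 * a + 2 * rn
  c2 <- a + 2 * rn + adotr / a
  gF <- c(c1 * r[1] - c2 * r0[1], c1 * r[2] - c2 * r0[2], c1 * r[3] - c2 * r0[3])
  qx <- c(q[2] * r0[3] - q[3] * r0[2],
          q[3] * r0[1] - q[1] * r0[3],
          q[1] * r0[2] - q[2] * r0[1])
  qxdotr <- qx[1] * r[1] + qx[2] * r[2] + qx[3] * r[3]
  (mu0 / (4 * pi * F^2)) * (F * qx - qxdotr * gF)
}

# Fixture loaders.
load_group_fixture <- function() {
  path <- system.file("extdata", "toy_group_power.csv", package = "megpls")
  df <- read.csv(path, stringsAsFactors = FALSE)
  list(X = as.matrix(df[, c("f1", "f2", "f3", "f4")]),
       groups = factor(df$group))
}

load_behavior_fixture <- function() {
  path <- system.file("extdata", "toy_behavior.csv", package = "megpls")
  df <- read.csv(path, stringsAsFactors = FALSE)
  list(X = as.matrix(df[, c("f1", "f2", "f3")]),
       Y = as.matrix(df[, c("v1", "v2")]))
}

# A small planted-effect cohort used by several tests.
small_cohort <- function(seed, contrast_effect = 1.0,
                         n_per_group = c(20, 20, 20), n_sources = 50,
                         loadings = NULL, mri_per_group = c(13, 20, 13)) {
  cfg <- synthetic_cohort_config(
    n_per_group = n_per_group, n_sources = n_sources,
    contrast_effect = contrast_effect, latent_loadings = loadings,
    mri_per_group = mri_per_group, seed = seed)
  generate_power_cohort(cfg)
}
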