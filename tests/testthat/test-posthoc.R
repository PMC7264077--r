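# Salience-map correlations, tail-power associations, brain-score/volume
# correlations and the neonatal regressions.

test_that("z-map correlation is exact, symmetric and affine-invariant", {
  set.seed(81)
  z1 <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, canonical_bands()$name))
  z2 <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, canonical_bands()$name))
  expect_equal(correlate_zmaps(z1, z1), 1)
  expect_equal(correlate_zmaps(z1, -z1), -1)
  expect_equal(correlate_zmaps(z1, z2),
               oracle_pearson(as.vector(z1), as.vector(z2)),
               tolerance = 1e-12)
  expect_equal(correlate_zmaps(z1, z2), correlate_zmaps(z2, z1))
  expect_equal(correlate_zmaps(3 * z1 + 2, 0.5 * z2 - 1),
               correlate_zmaps(z1, z2), tolerance = 1e-12)
  expect_error(correlate_zmaps(z1, z2[1:4, ]), "dimensions")
})

test_that("bias-corrected skewness matches the reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(82)
  for (i in 1:5) {
    x <- rexp(30 + i) - i / 3
    expect_equal(megpls:::sample_skewness(x), e1071::skewness(x, type = 2),
                 tolerance = 1e-12)
  }
})

make_power <- function(values, n_sources, bands = canonical_bands()) {
  band_power_matrix(values, n_sources = n_sources, bands = bands)
}

test_that("tail selection count and side follow the documented rules", {
  set.seed(83)
  ns <- 200
  nb <- 5
  # symmetric z-scores with one extreme negative outlier per band
  z <- matrix(rnorm(ns * nb), ns, nb, dimnames = list(NULL, canonical_bands()$name))
  z[7, ] <- -25
  raw <- matrix(rexp(20 * ns * nb), 20, ns * nb)
  P <- matrix(0, 20, ns * nb)
  for (s in seq_len(ns)) {
    cols <- ((s - 1) * nb + 1):(s * nb)
    P[, cols] <- raw[, cols] / rowSums(raw[, cols, drop = FALSE])
  }
  power <- make_power(P, ns)
  cov <- rnorm(20)
  res <- tail_power_association(z, power, cov, fraction = 0.025)
  for (b in seq_len(nb)) {
    expect_length(res[[b]]$selected_sources, 5)     # ceil(0.025 * 200)
    expect_equal(res[[b]]$tail, "negative")         # outlier skews negative
    expect_true(7 %in% res[[b]]$selected_sources)
  }
  # positive skew selects the positive tail
  z2 <- z; z2[7, ] <- 60
  res2 <- tail_power_association(z2, power, cov, fraction = 0.025)
  expect_equal(res2[[1]]$tail, "positive")
  expect_true(7 %in% res2[[1]]$selected_sources)
  # selection count formula across fractions
  for (fr in c(0.01, 0.025, 0.1, 0.33))
    expect_length(tail_power_association(z, power, cov,
                                         fraction = fr)[[1]]$selected_sources,
                  ceiling(fr * ns))
  expect_error(tail_power_association(z, power, cov, fraction = 0.6),
               "fraction")
})

test_that("tied z-scores break deterministically by ascending source index", {
  ns <- 40
  z <- matrix(0, ns, 5, dimnames = list(NULL, canonical_bands()$name))
  z[, ] <- rep(c(-1, -1, -1, 0), length.out = ns)   # many ties at the cutoff
  z[2, ] <- -30                                     # force negative skew
  raw <- matrix(rexp(10 * ns * 5), 10, ns * 5)
  P <- matrix(0, 10, ns * 5)
  for (s in seq_len(ns)) {
    cols <- ((s - 1) * 5 + 1):(s * 5)
    P[, cols] <- raw[, cols] / rowSums(raw[, cols, drop = FALSE])
  }
  power <- make_power(P, ns)
  r1 <- tail_power_association(z, power, rnorm(10), fraction = 0.1)
  r2 <- tail_power_association(z, power, rnorm(10), fraction = 0.1)
  expect_identical(r1[[1]]$selected_sources, r2[[1]]$selected_sources)
  # ties after the forced extreme resolve to the lowest source indices
  sel <- r1[[1]]$selected_sources
  expect_equal(sel[1:2], c(1, 2))
})

test_that("pooled correlation exceeds within-group correlations for group-separated data", {
  # covariate and tail power share a between-group gradient plus weak
  # within-group coupling: pooling the groups raises the correlation
  set.seed(84)
  ns <- 40; nb <- 5; npg <- 15
  g <- factor(rep(c("ELGA", "VLGA", "Term"), each = npg))
  shift <- rep(c(2, 0, -2), each = npg)
  cov <- shift + rnorm(3 * npg)
  z <- matrix(rnorm(ns * nb), ns, nb, dimnames = list(NULL, canonical_bands()$name))
  z[1:4, ] <- 8   # positive tail = sources 1:4
  lat <- 0.3 * scale(cov)[, 1] + 0.1 * rnorm(3 * npg)
  logits <- matrix(rnorm(3 * npg * ns * nb, 0, 0.1), 3 * npg, ns * nb)
  sal_cols <- as.vector(vapply(1:4, function(s) (s - 1) * nb + 1:2, numeric(2)))
  logits[, sal_cols] <- logits[, sal_cols] + lat
  P <- matrix(0, 3 * npg, ns * nb)
  for (s in seq_len(ns)) {
    cols <- ((s - 1) * nb + 1):(s * nb)
    ez <- exp(logits[, cols]); P[, cols] <- ez / rowSums(ez)
  }
  res <- tail_power_association(z, make_power(P, ns), cov, groups = g,
                                fraction = 0.1)
  tb <- res[["delta"]]$correlations
  pooled <- abs(tb$r[tb$group == "all"])
  within <- abs(tb$r[tb$group != "all"])
  expect_true(all(pooled > within))
})

test_that("brain-score/volume correlations behave at the closed-form limits", {
  set.seed(85)
  sc <- rnorm(20)
  TV <- 3 * sc + 5            # exactly proportional
  CGV <- rnorm(20)
  out <- correlate_scores_with_volumes(sc, TV, CGV)
  expect_equal(out$r[out$variable == "TV"], 1, tolerance = 1e-12)
  expect_lt(out$p[out$variable == "TV"], 1e-10)
  expect_error(correlate_scores_with_volumes(sc, rep(1, 20), CGV),
               "zero variance")
  expect_error(correlate_scores_with_volumes(sc[1:3], TV[1:3], CGV[1:3]),
               "fewer than 4")
})

test_that("the shuffled-covariate null matches the analytic mean |r| for n = 10", {
  set.seed(86)
  n <- 10
  sc <- rnorm(n)
  TV <- rnorm(n)
  rs <- vapply(1:1000, function(i) {
    cor(sc, sample(TV))
  }, numeric(1))
  # |r| under the null: |r| = sqrt(B), B ~ Beta(1/2, (n-2)/2)
  analytic <- exp(lbeta(1, (n - 2) / 2) - lbeta(1 / 2, (n - 2) / 2))
  expect_equal(mean(rs), 0, tolerance = 0.035)
  expect_equal(mean(abs(rs)), analytic, tolerance = 0.03)
})

test_that("the neonatal regression honours the df contract and matches OLS oracles", {
  sim <- small_cohort(seed = 87, n_per_group = c(13, 24, 13),
                      mri_per_group = c(13, 24, 13))
  reg <- neonatal_regression(sim$cohort, "TI")
  expect_equal(reg$n, 37)
  expect_equal(reg$df1, 7)
  expect_equal(reg$df2, 29)
  expect_true(reg$r_squared >= 0 && reg$r_squared <= 1)
  # normal-equations oracle on the same complete cases
  cc <- sim$cohort[complete.cases(sim$cohort[, c("TI", "GA", "sex", "infection",
                                                 "SNAP", "morphine", "pain")]), ]
  Xd <- cbind(1, cc$GA, cc$sex, cc$infection, cc$SNAP, cc$morphine, cc$pain,
              cc$sex * cc$GA)
  beta_oracle <- oracle_ols(Xd, cc$TI)
  expect_equal(unname(reg$coefficients$beta),
               beta_oracle[c(2:7, 8)], tolerance = 1e-8)
  expect_equal(reg$intercept, beta_oracle[1], tolerance = 1e-8)
  # TV-CGV outcome runs on the same cases
  reg2 <- neonatal_regression(sim$cohort, "TV_CGV")
  expect_equal(reg2$df2, reg2$n - 8)
})

test_that("noise-free linear outcomes are recovered exactly", {
  sim <- small_cohort(seed = 88, n_per_group = c(13, 24, 13),
                      mri_per_group = c(13, 24, 13))
  co <- sim$cohort
  co$TI <- 40 + 1.75 * co$GA          # exact linear in GA
  reg <- suppressWarnings(neonatal_regression(co, "TI"))  # lm perfect-fit note
  expect_equal(reg$r_squared, 1, tolerance = 1e-10)
  expect_equal(reg$coefficients$beta[reg$coefficients$term == "GA"], 1.75,
               tolerance = 1e-8)
})

test_that("perfect collinearity raises a rank-deficiency error", {
  sim <- small_cohort(seed = 89, n_per_group = c(13, 24, 13),
                      mri_per_group = c(13, 24, 13))
  co <- sim$cohort
  co$pain <- 2 * co$morphine
  expect_error(neonatal_regression(co, "TI"), "collinear")
})

test_that("generating coefficients are recovered within 2 SE in most replicates", {
  # structural TI coupling switched off so the fitted model is the
  # generating model; 25 seeded replicates, all seven predictors
  sp <- megpls:::.default_structural_params()
  sp$TI$coupling <- 0
  hits <- 0; total <- 0
  for (s in 1:25) {
    cfg <- synthetic_cohort_config(n_per_group = c(13, 24, 13),
                                   mri_per_group = c(13, 24, 13),
                                   n_sources = 5, structural_params = sp,
                                   seed = 900 + s)
    sim <- generate_power_cohort(cfg)
    reg <- neonatal_regression(sim$cohort, "TI")
    se <- summary(reg$fit)$coefficients[c("GA", "sex", "infection", "SNAP",
                                          "morphine", "pain", "GA:sex"),
                                        "Std. Error"]
    beta_gen <- sim$truth$generating_coefficients
    hits <- hits + sum(abs(reg$coefficients$beta - beta_gen) <= 2 * se)
    total <- total + length(beta_gen)
  }
  # +-2 SE covers ~94.6% nominally at 29 df; allow 3-sigma Monte-Carlo slack
  # around that nominal rate for 175 coefficient draws
  expect_gte(hits / total, 0.89)
})
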