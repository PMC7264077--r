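# Mean-centered and behavioral PLS: point estimates against closed forms and
# dense SVD oracles, resampling inference, brain scores, invariants.

test_that("identical group means give all-zero singular values", {
  X <- rbind(matrix(1:8, 2, 4, byrow = TRUE),
             matrix(1:8, 2, 4, byrow = TRUE),
             matrix(1:8, 2, 4, byrow = TRUE))
  g <- factor(rep(c("a", "b", "c"), each = 2))
  res <- mean_centered_pls(X, g)
  expect_true(all(res$singular_values < 1e-12))
})

test_that("two groups, one feature: closed-form 1x2 decomposition", {
  X <- matrix(c(0, 0, 2, 2), 4, 1)
  g <- factor(rep(c("a", "b"), each = 2))
  res <- mean_centered_pls(X, g)
  # centered group means (-1, 1): singular value sqrt(2), salience +-1,
  # contrast +-(1, -1)/sqrt(2)
  expect_equal(res$singular_values[1], sqrt(2), tolerance = 1e-12)
  expect_equal(unname(abs(res$saliences[1, 1])), 1, tolerance = 1e-12)
  expect_equal(unname(sort(abs(res$contrasts[, 1]))), rep(1 / sqrt(2), 2),
               tolerance = 1e-12)
})

test_that("mean-centered point estimates match a dense SVD oracle on the fixture", {
  fx <- load_group_fixture()
  res <- mean_centered_pls(fx$X, fx$groups)
  M <- oracle_group_means(fx$X, fx$groups)
  Mc <- M - matrix(colMeans(M), nrow(M), ncol(M), byrow = TRUE)
  orc <- oracle_svd(t(Mc))                    # features x groups
  expect_equal(res$singular_values, orc$d, tolerance = 1e-10)
  for (j in 1:2) {                            # sign-insensitive comparison
    s <- sign(sum(res$saliences[, j] * orc$u[, j]))
    expect_equal(res$saliences[, j], s * orc$u[, j],
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(res$contrasts[, j], s * orc$v[, j],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # unit-norm singular vectors, non-increasing singular values
  expect_equal(unname(colSums(res$saliences^2)), rep(1, 3), tolerance = 1e-10)
  expect_equal(unname(colSums(res$contrasts^2)), rep(1, 3), tolerance = 1e-10)
  expect_true(all(diff(res$singular_values) <= 1e-12))
})

test_that("behavioral PLS: planted exact correlations give closed-form results", {
  # orthogonal noise-free case: singular value 0
  X <- matrix(c(1, -1, 1, -1), 4, 1)
  Y <- matrix(c(1, 1, -1, -1), 4, 1)
  expect_lt(behavioral_pls(X, Y)$singular_values[1], 1e-12)
  # exact r = -0.5 via Gram-Schmidt construction: singular value 0.5
  x <- as.vector(scale(1:8))
  e <- as.vector(scale(resid(lm(rnorm(8) ~ x))))
  y <- -0.5 * x + sqrt(0.75) * e
  res <- behavioral_pls(matrix(x), matrix(y))
  expect_equal(res$singular_values[1], 0.5, tolerance = 1e-10)
  expect_equal(abs(res$contrasts[1, 1]), 1, tolerance = 1e-12)
})

test_that("behavioral PLS matches a dense SVD oracle on the copied-feature fixture", {
  fx <- load_behavior_fixture()
  res <- behavioral_pls(fx$X, fx$Y)
  R <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) R[i, j] <- oracle_pearson(fx$X[, i], fx$Y[, j])
  orc <- oracle_svd(R)
  expect_equal(res$singular_values, orc$d[1:2], tolerance = 1e-10)
  for (j in 1:2) {
    s <- sign(sum(res$contrasts[, j] * orc$v[, j]))
    expect_equal(unname(res$contrasts[, j]), s * orc$v[, j], tolerance = 1e-10)
  }
  # v1 copies feature 2, so LV1 loads on v1 almost entirely
  expect_gt(abs(res$contrasts["v1", 1]), 0.9)
})

test_that("constant features and variables are rejected by name", {
  X <- cbind(a = rnorm(10), b = rep(1, 10))
  Y <- cbind(v = rnorm(10))
  expect_error(behavioral_pls(X, Y), "b")
  expect_error(behavioral_pls(X[, 1, drop = FALSE], cbind(cv = rep(2, 10))),
               "cv")
})

test_that("permutation p-values follow the smoothed counting rule", {
  set.seed(51)
  # strong planted separation: observed exceeds every permutation
  X <- rbind(matrix(rnorm(10 * 4, 5), 10, 4), matrix(rnorm(10 * 4, 0), 10, 4),
             matrix(rnorm(10 * 4, -5), 10, 4))
  g <- factor(rep(c("a", "b", "c"), each = 10))
  pt <- permutation_test(X, g, n_perm = 499, seed = 52)
  expect_equal(pt$p_values[1], 1 / 500)
  # label-invariant data: everything ties at zero, p = 1
  X0 <- matrix(1, 30, 4) + 0
  pt0 <- permutation_test(X0, g, n_perm = 199, seed = 53)
  expect_equal(pt0$p_values[1], 1)
  expect_warning(permutation_test(X, g, n_perm = 50, seed = 1), "coarse")
})

test_that("bootstrap conventions: degenerate features and noise-free groups", {
  set.seed(54)
  X <- cbind(rnorm(12), rep(0, 12), rnorm(12))
  g <- factor(rep(c("a", "b", "c"), each = 4))
  bi <- bootstrap_inference(X, g, n_boot = 120, seed = 55)
  expect_equal(unname(bi$bootstrap_ratios[2, ]), rep(0, 3))
  # all subjects identical within group: every resample identical
  Mg <- rbind(c(1, 2, 0), c(5, 3, 1), c(2, 0, 4))
  Xc <- Mg[rep(1:3, each = 4), ]
  bic <- bootstrap_inference(Xc, g, n_boot = 110, seed = 56)
  expect_true(all(bic$salience_se < 1e-12))
  expect_true(all(bic$bootstrap_ratios == 0))
  expect_equal(bic$contrast_ci_lower, bic$contrast_ci_upper, tolerance = 1e-12)
  expect_equal(bic$contrast_ci_lower, unclass(bic$point$contrasts),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("bootstrap-ratio signs recover the planted salience where it is strong", {
  sim <- small_cohort(seed = 57)
  bi <- bootstrap_inference(sim$power, sim$cohort$group, n_boot = 300,
                            seed = 58)
  planted <- as.vector(t(sim$truth$planted_salience))
  strong <- abs(planted) >= quantile(abs(planted[planted != 0]), 0.9)
  agree <- sign(bi$bootstrap_ratios[strong, 1]) == sign(planted[strong])
  expect_gte(mean(agree), 0.9)
})

test_that("brain scores are exact dot products", {
  X <- diag(4)
  U <- cbind(c(1, 0, 0, 0))
  expect_equal(unname(brain_scores(X, U)[, 1]), X[, 1])
  set.seed(59)
  X2 <- matrix(rnorm(6 * 5), 6, 5)
  U2 <- matrix(rnorm(5 * 2), 5, 2)
  expect_equal(unname(brain_scores(X2, U2)), oracle_brain_scores(X2, U2),
               tolerance = 1e-12)
  X3 <- X2; X3[2, ] <- 2 * X2[2, ]
  expect_equal(brain_scores(X3, U2)[2, ], 2 * brain_scores(X2, U2)[2, ])
  expect_error(brain_scores(X2, matrix(0, 4, 2)), "do not match")
})

test_that("singular-value energy equals the squared Frobenius norm", {
  fx <- load_group_fixture()
  res <- mean_centered_pls(fx$X, fx$groups)
  M <- oracle_group_means(fx$X, fx$groups)
  Mc <- M - matrix(colMeans(M), nrow(M), ncol(M), byrow = TRUE)
  expect_equal(sum(res$singular_values^2), sum(Mc^2), tolerance = 1e-10)
  bx <- load_behavior_fixture()
  resb <- behavioral_pls(bx$X, bx$Y)
  expect_equal(sum(resb$singular_values^2), sum(cor(bx$X, bx$Y)^2),
               tolerance = 1e-10)
})

test_that("mean-centered PLS is invariant to subject order and feature shifts", {
  fx <- load_group_fixture()
  res <- mean_centered_pls(fx$X, fx$groups)
  set.seed(60)
  ord <- sample(nrow(fx$X))
  res2 <- mean_centered_pls(fx$X[ord, ], fx$groups[ord])
  expect_equal(res$singular_values, res2$singular_values, tolerance = 1e-12)
  # LV3 spans the null space (singular value ~0, arbitrary direction)
  expect_equal(res$saliences[, 1:2], res2$saliences[, 1:2], tolerance = 1e-12)
  X3 <- fx$X; X3[, 2] <- X3[, 2] + 100
  res3 <- mean_centered_pls(X3, fx$groups)
  expect_equal(res$singular_values, res3$singular_values, tolerance = 1e-10)
  expect_equal(res$saliences[, 1:2], res3$saliences[, 1:2], tolerance = 1e-8)
})

test_that("behavioral PLS is invariant to affine rescaling of variables (up to sign)", {
  bx <- load_behavior_fixture()
  res <- behavioral_pls(bx$X, bx$Y)
  Y2 <- bx$Y
  Y2[, 1] <- -3 * Y2[, 1] + 7
  Y2[, 2] <- 0.01 * Y2[, 2] - 2
  res2 <- behavioral_pls(bx$X, Y2)
  expect_equal(res$singular_values, res2$singular_values, tolerance = 1e-10)
  for (j in 1:2)
    expect_equal(abs(res2$contrasts[, j]), abs(res$contrasts[, j]),
                 tolerance = 1e-10)
})

test_that("group-mean brain scores align with contrast times singular value", {
  # noise-free: subjects identical within group
  M <- rbind(c(1, 0, 2), c(0, 1, 1), c(2, 2, 0))   # group means, 3 features
  X <- M[rep(1:3, each = 3), ]
  g <- factor(rep(c("a", "b", "c"), each = 3))
  res <- mean_centered_pls(X, g)
  Xc <- sweep(X, 2L, colMeans(M))                  # center by grand group mean
  sc <- brain_scores(Xc, res$saliences)
  for (j in 1:2) {
    gm <- tapply(sc[, j], g, mean)
    expect_equal(unname(gm), res$contrasts[, j] * res$singular_values[j],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("groups smaller than two are rejected", {
  X <- matrix(rnorm(12), 6, 2)
  expect_error(mean_centered_pls(X, factor(c("a", rep("b", 5)))), "n >= 2")
})

test_that("run_pls is reproducible and carries the full inference set", {
  sim <- small_cohort(seed = 61, n_per_group = c(8, 8, 8), n_sources = 6)
  r1 <- run_pls(sim$power, groups = sim$cohort$group, n_perm = 120,
                n_boot = 120, seed = 62)
  r2 <- run_pls(sim$power, groups = sim$cohort$group, n_perm = 120,
                n_boot = 120, seed = 62)
  expect_identical(r1$p_values, r2$p_values)
  expect_identical(r1$bootstrap_ratios, r2$bootstrap_ratios)
  expect_true(all(r1$p_values >= 0 & r1$p_values <= 1))
  expect_equal(dim(r1$brain_scores), c(24, 3))
  expect_s3_class(zmap(r1), "zmap")
  expect_equal(dim(zmap(r1)), c(6, 5))
})
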