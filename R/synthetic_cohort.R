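# Synthetic cohort generation.
#
# Cohorts are generated directly at the level the statistical analyses
# consume: a subjects x (sources x bands) relative-power matrix plus a
# cohort table of group labels, neurocognitive outcomes, structural and
# neonatal variables. Effects are planted on unconstrained logits of the
# per-source band powers and renormalized through a softmax, so the
# compositional sum-to-one property of relative power holds by construction.
# The ground truth (planted salience, contrast, latent scores, generating
# regression coefficients) is returned alongside for recovery testing.

.default_outcome_table <- function() {
  # 11 school-age outcome scores: four WISC indices, two CBCL scales, two
  # BRIEF indices and three BEERY subscales. Positive scores mean better
  # outcome for WISC/BEERY and worse outcome for CBCL/BRIEF, so loadings on
  # a "slowing" brain factor default to negative for the former and positive
  # for the latter. Means/SDs follow the standardization of the instruments.
  data.frame(
    name    = c("VIQ", "IQ_PR", "IQ_WM", "IQ_PSI",
                "CBCL_INT", "CBCL_EXT", "BRIEF_BRI", "BRIEF_MCI",
                "BEERY_VMI", "BEERY_VP", "BEERY_MC"),
    mean    = c(100, 100, 100, 100, 50, 50, 50, 50, 100, 100, 100),
    sd      = c(15, 15, 15, 15, 10, 10, 11, 12, 11, 15, 11),
    loading = c(-0.35, -0.35, -0.30, -0.30, 0.20, 0.15, 0.20, 0.25,
                -0.30, -0.30, -0.25),
    stringsAsFactors = FALSE
  )
}

.default_structural_params <- function() {
  # Group means/SDs for the structural variables (rows ELGA, VLGA, Term) and
  # the coupling (correlation) of each variable with the latent brain factor.
  # Volumes in mm^3, intensities on the normalized 0-255 scale.
  list(
    TV  = list(mean = c(6951, 7494, 8268), sd = c(697, 745, 603),
               coupling = -0.4),
    CGV = list(mean = c(536606, 555204, 589950), sd = c(40984, 57458, 60300),
               coupling = 0),
    ICV = list(mean = c(1515881, 1534179, 1589423),
               sd = c(122911, 142595, 58071), coupling = 0),
    TI  = list(mean = c(88.0, 89.2, 89.5), sd = c(1.8, 1.6, 1.5),
               coupling = -0.5, residual_sd = 1.2),
    CGI = list(mean = c(88.0, 91.5, 88.0), sd = c(8.7, 8.2, 6.7),
               coupling = 0.3),
    CWI = list(mean = c(108, 114.7, 110), sd = c(7.9, 10.3, 8.5),
               coupling = 0.3)
  )
}

.default_neonatal_betas <- function() {
  # Generating coefficients of the thalamic-intensity model: GA (weeks),
  # sex (0/1), infection (0/1), SNAP day-1 score, log-transformed cumulative
  # morphine dose, log-transformed count of skin-breaking procedures, and the
  # sex x GA interaction.
  c(GA = -0.104, sex = -14.14, infection = -1.084, SNAP = -0.009,
    morphine = -2.948, pain = -0.064, sex_GA = 0.487)
}

#' Default planted salience map
#'
#' A spectral "slowing" pattern on a contiguous fraction of sources: raised
#' delta and theta, lowered alpha and beta, unchanged gamma, normalized to
#' unit Euclidean norm over all source-by-band weights.
#'
#' @param n_sources Number of source locations.
#' @param bands Band definition data frame.
#' @param active_fraction Fraction of sources carrying the effect.
#' @return An `n_sources` by `nrow(bands)` matrix with unit Frobenius norm.
#' @export
default_planted_salience <- function(n_sources, bands = canonical_bands(),
                                     active_fraction = 0.3) {
  bands <- validate_bands(bands)
  weights <- c(delta = 1, theta = 0.5, alpha = -1, beta = -0.5, gamma = 0)
  bw <- weights[bands$name]
  if (anyNA(bw)) bw <- rep_len(c(1, -1), nrow(bands))  # non-canonical bands
  s <- matrix(0, n_sources, nrow(bands),
              dimnames = list(NULL, bands$name))
  active <- seq_len(max(1L, ceiling(active_fraction * n_sources)))
  s[active, ] <- matrix(bw, length(active), nrow(bands), byrow = TRUE)
  s / sqrt(sum(s^2))
}

#' Configure a synthetic cohort
#'
#' Bundles and validates every parameter of the cohort generator. Defaults
#' emulate a three-group school-age cohort (23 extremely-preterm-like, 36
#' very-preterm-like, 39 term-born-like children) with a planted spectral
#' slowing contrast in the first group, eleven outcome scores coupled to the
#' brain pattern through a single latent factor, structural variables with
#' group differences and brain coupling, and neonatal predictors with a
#' planted linear effect on thalamic intensity.
#'
#' @param n_per_group Integer vector of three group sizes (ELGA-like,
#'   VLGA-like, term-like). All must be at least 2.
#' @param n_sources Number of source-grid locations.
#' @param bands Band definition data frame.
#' @param contrast_effect Group-mean shift of the first group along the
#'   planted salience, on the logit scale of band power.
#' @param planted_salience Optional `n_sources` by `nrow(bands)` matrix of
#'   signed weights; normalized to unit Frobenius norm. Defaults to
#'   [default_planted_salience()].
#' @param latent_loadings Named vector of target correlations (in \[-1, 1\])
#'   between each outcome variable and the latent brain factor. Defaults to
#'   a slowing-versus-outcome pattern over the 11 canonical scores.
#' @param structural_params List of per-variable group means, SDs and
#'   latent-factor couplings for TV, CGV, ICV, TI, CGI, CWI.
#' @param neonatal_betas Named vector of generating coefficients of the
#'   thalamic-intensity model (GA, sex, infection, SNAP, morphine, pain,
#'   sex_GA).
#' @param noise_sd Residual SD of each band-power logit. Must be positive.
#' @param latent_sd SD of the subject-level latent amplitude expressing the
#'   planted brain pattern.
#' @param mri_per_group Number of subjects per group with structural (MRI)
#'   measures; neonatal variables are recorded for preterm subjects with MRI.
#' @param seed Integer seed (mandatory); identical configurations reproduce
#'   cohorts bit-identically.
#' @return An object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_per_group = c(23, 36, 39),
                                    n_sources = 50,
                                    bands = canonical_bands(),
                                    contrast_effect = 1.0,
                                    planted_salience = NULL,
                                    latent_loadings = NULL,
                                    structural_params = .default_structural_params(),
                                    neonatal_betas = .default_neonatal_betas(),
                                    noise_sd = 0.15,
                                    latent_sd = 0.5,
                                    mri_per_group = c(13, 24, 13),
                                    seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  bands <- validate_bands(bands)
  if (length(n_per_group) != 3L || any(n_per_group < 2L))
    stop("`n_per_group` must give three group sizes, all >= 2")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (is.null(planted_salience))
    planted_salience <- default_planted_salience(n_sources, bands)
  planted_salience <- as.matrix(planted_salience)
  if (nrow(planted_salience) != n_sources ||
      ncol(planted_salience) != nrow(bands))
    stop("`planted_salience` must be ", n_sources, " x ", nrow(bands),
         " to match n_sources and bands")
  nrm <- sqrt(sum(planted_salience^2))
  if (nrm == 0) stop("`planted_salience` must be non-zero")
  planted_salience <- planted_salience / nrm
  outcome_table <- .default_outcome_table()
  if (!is.null(latent_loadings)) {
    if (is.null(names(latent_loadings)))
      stop("`latent_loadings` must be named by outcome variable")
    unknown <- setdiff(names(latent_loadings), outcome_table$name)
    if (length(unknown))
      stop("unknown outcome variable(s): ", paste(unknown, collapse = ", "))
    outcome_table$loading <- 0
    outcome_table$loading[match(names(latent_loadings), outcome_table$name)] <-
      unname(latent_loadings)
  }
  if (any(abs(outcome_table$loading) > 1))
    stop("latent loadings are correlations and must lie in [-1, 1]")
  mri_per_group <- pmin(as.integer(mri_per_group), as.integer(n_per_group))
  structure(
    list(n_per_group = as.integer(n_per_group), n_sources = as.integer(n_sources),
         bands = bands, contrast_effect = contrast_effect,
         planted_salience = planted_salience, outcome_table = outcome_table,
         structural_params = structural_params, neonatal_betas = neonatal_betas,
         noise_sd = noise_sd, latent_sd = latent_sd,
         mri_per_group = mri_per_group, seed = as.integer(seed)),
    class = "synthetic_cohort_config"
  )
}

# Baseline band-power logits shared by every source: a typical school-age
# resting composition (delta-dominant with a clear alpha share).
.baseline_logits <- function(bands) {
  ref <- c(delta = 0.32, theta = 0.23, alpha = 0.22, beta = 0.15, gamma = 0.08)
  p <- ref[bands$name]
  if (anyNA(p)) p <- rep(1 / nrow(bands), nrow(bands))
  log(unname(p))
}

.group_levels <- c("ELGA", "VLGA", "Term")

#' Generate a synthetic cohort of relative band power and clinical variables
#'
#' Draws a cohort under the configured generative model. Band-power effects
#' are planted on per-feature logits (group shift along the planted salience
#' for the first group, plus a subject-level latent amplitude and independent
#' feature noise) and softmax-renormalized per source, so each subject/source
#' power vector is non-negative and sums to one. Outcome variables are
#' correlated with the subjects' realized projections on the planted salience
#' (the latent scores); structural variables carry group differences and
#' latent coupling; thalamic intensity of preterm subjects additionally
#' carries the configured neonatal linear effects.
#'
#' @param config A [synthetic_cohort_config()].
#' @return A list with components `power` (a `band_power_matrix`: subjects by
#'   source-band features), `cohort` (a data frame of group, outcome,
#'   structural and neonatal variables) and `truth` (a `synthetic_truth`
#'   list: `planted_salience`, `planted_contrast`, `latent_scores`,
#'   `generating_coefficients`).
#' @export
generate_power_cohort <- function(config) {
  if (!inherits(config, "synthetic_cohort_config"))
    stop("`config` must be created by synthetic_cohort_config()")
  set.seed(config$seed)
  ns <- config$n_sources
  bands <- config$bands
  nb <- nrow(bands)
  nf <- ns * nb
  npg <- config$n_per_group
  n <- sum(npg)
  group <- factor(rep(.group_levels, npg), levels = .group_levels)

  # feature-space salience vector, source-major order to match feature_names()
  sal <- as.vector(t(config$planted_salience))
  b0 <- rep(.baseline_logits(bands), ns)

  shift <- config$contrast_effect * as.numeric(group == "ELGA")
  u <- stats::rnorm(n, 0, config$latent_sd)
  E <- matrix(stats::rnorm(n * nf, 0, config$noise_sd), n, nf)
  Z <- outer(shift + u, sal) + E
  Z <- sweep(Z, 2L, b0, "+")

  # realized latent score: projection of the logit deviation on the salience
  latent <- as.vector((Z - matrix(b0, n, nf, byrow = TRUE)) %*% sal)
  t_std <- as.vector(scale(latent))

  # softmax per source block
  P <- matrix(0, n, nf)
  for (s in seq_len(ns)) {
    cols <- ((s - 1L) * nb + 1L):(s * nb)
    ez <- exp(Z[, cols, drop = FALSE])
    P[, cols] <- ez / rowSums(ez)
  }
  colnames(P) <- feature_names(ns, bands)
  power <- band_power_matrix(P, n_sources = ns, bands = bands)

  cohort <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    group = group, stringsAsFactors = FALSE
  )

  ot <- config$outcome_table
  for (v in seq_len(nrow(ot))) {
    lam <- ot$loading[v]
    y <- lam * t_std + sqrt(1 - lam^2) * stats::rnorm(n)
    cohort[[ot$name[v]]] <- ot$mean[v] + ot$sd[v] * y
  }

  # structural subset (per-group seeded sample) and neonatal variables
  has_mri <- logical(n)
  for (g in seq_along(.group_levels)) {
    idx <- which(group == .group_levels[g])
    has_mri[sample(idx, config$mri_per_group[g])] <- TRUE
  }
  cohort$has_mri <- has_mri
  gi <- as.integer(group)
  sp <- config$structural_params
  draw_structural <- function(par) {
    rho <- par$coupling
    x <- par$mean[gi] + par$sd[gi] *
      (rho * t_std + sqrt(1 - rho^2) * stats::rnorm(n))
    ifelse(has_mri, x, NA_real_)
  }
  cohort$TV  <- draw_structural(sp$TV)
  cohort$CGV <- draw_structural(sp$CGV)
  cohort$ICV <- draw_structural(sp$ICV)
  cohort$CGI <- draw_structural(sp$CGI)
  cohort$CWI <- draw_structural(sp$CWI)

  # neonatal predictors: preterm subjects with MRI, mirroring the typical
  # availability of chart-review data alongside usable structural scans
  neonatal <- has_mri & group != "Term"
  GA <- sex <- infection <- SNAP <- morphine <- pain <- rep(NA_real_, n)
  iE <- which(neonatal & group == "ELGA")
  iV <- which(neonatal & group == "VLGA")
  GA[iE] <- pmin(pmax(stats::rnorm(length(iE), 27.1, 1.36), 24), 28)
  GA[iV] <- pmin(pmax(stats::rnorm(length(iV), 31.0, 1.20), 29), 32)
  idx <- which(neonatal)
  sex[idx] <- stats::rbinom(length(idx), 1L, 0.5)
  infection[iE] <- stats::rbinom(length(iE), 1L, 7 / 13)
  infection[iV] <- stats::rbinom(length(iV), 1L, 20 / 23)
  SNAP[iE] <- pmax(stats::rnorm(length(iE), 22.5, 9.73), 0)
  SNAP[iV] <- pmax(stats::rnorm(length(iV), 5.6, 7.5), 0)
  morphine[iE] <- log1p(pmax(stats::rnorm(length(iE), 2.7, 5.74), 0))
  morphine[iV] <- log1p(pmax(stats::rnorm(length(iV), 0.06, 0.18), 0))
  pain[iE] <- log(pmax(stats::rnorm(length(iE), 153.6, 68.7), 5))
  pain[iV] <- log(pmax(stats::rnorm(length(iV), 65.1, 50.9), 5))
  cohort$GA <- GA; cohort$sex <- sex; cohort$infection <- infection
  cohort$SNAP <- SNAP; cohort$morphine <- morphine; cohort$pain <- pain

  # thalamic intensity: neonatal linear part for preterm subjects (centered
  # so group means stay near the configured values), latent coupling + noise
  beta <- config$neonatal_betas
  ti_par <- sp$TI
  res_sd <- if (!is.null(ti_par$residual_sd)) ti_par$residual_sd else ti_par$sd[1]
  rho <- ti_par$coupling
  TI <- rep(NA_real_, n)
  lin <- rep(0, n)
  if (length(idx)) {
    Xn <- cbind(GA = GA[idx], sex = sex[idx], infection = infection[idx],
                SNAP = SNAP[idx], morphine = morphine[idx], pain = pain[idx],
                sex_GA = sex[idx] * GA[idx])
    lp <- as.vector(Xn %*% beta[colnames(Xn)])
    lin[idx] <- lp - mean(lp)
  }
  zi <- stats::rnorm(n)
  TI_all <- ti_par$mean[gi] + lin +
    res_sd * (rho * t_std + sqrt(1 - rho^2) * zi)
  TI[has_mri] <- TI_all[has_mri]
  cohort$TI <- TI
  # keep column order: structural block together
  cohort <- cohort[, c("subject_id", "group", ot$name, "has_mri",
                       "TV", "CGV", "ICV", "TI", "CGI", "CWI",
                       "GA", "sex", "infection", "SNAP", "morphine", "pain")]

  contrast <- c(1, 0, 0) - 1 / 3
  truth <- structure(
    list(planted_salience = config$planted_salience,
         planted_contrast = contrast / sqrt(sum(contrast^2)),
         latent_scores = latent,
         latent_scores_std = t_std,
         generating_coefficients = beta,
         config = config),
    class = "synthetic_truth"
  )
  list(power = power, cohort = cohort, truth = truth)
}
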