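# Orchestration of the four headline analyses on one synthetic cohort:
#   1. mean-centered PLS on relative power (group differences)
#   2. behavioral PLS vs the 11 neurocognitive scores
#   3. behavioral PLS vs the three intensity variables + z-map correlation
#      against analysis 1
#   4. behavioral PLS vs the TV-CGV ratio + z-map correlation against
#      analysis 2, brain-score/volume correlations, tail-power associations
#      and the neonatal regressions
# All randomness derives from one master seed through a fixed per-stage
# offset, so a run is reproducible bit-identically from its manifest.

stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 0L, pls_group = 1L, pls_neuro = 2L,
               pls_intensity = 3L, pls_volume = 4L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) + 1000003 * offsets[[stage]]) %% (2^31 - 1))
}

#' Run the full synthetic study
#'
#' Generates (or accepts) a cohort and runs the four headline analyses with
#' permutation and bootstrap inference, the post-hoc salience-map
#' comparisons and the neonatal regressions, writing every result as CSV
#' into a run directory with a JSON manifest.
#'
#' @param config A [synthetic_cohort_config()]; its `seed` is overridden by
#'   the `seed` argument's cohort stage seed. `NULL` uses the generator
#'   defaults.
#' @param out_dir Run directory (created; existing files overwritten).
#' @param seed Master seed for all stages.
#' @param n_perm,n_boot Resampling counts per analysis (defaults 500).
#' @return Invisibly, a list with the cohort (`power`, `cohort`, `truth`),
#'   the four `pls_result`s, the post-hoc results and the manifest.
#' @export
run_full_study <- function(config = NULL, out_dir, seed = 1,
                           n_perm = 500, n_boot = 500) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  stage <- "configuration"
  run <- function(name, expr) {
    stage <- name
    tryCatch(expr, error = function(e)
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config))
    config <- synthetic_cohort_config(seed = stage_seed(seed, "cohort"))
  else
    config$seed <- stage_seed(seed, "cohort")

  sim <- run("simulate", generate_power_cohort(config))
  power <- sim$power; cohort <- sim$cohort
  validation <- run("validate", validate_cohort_table(cohort))
  write_band_power_csv(power, file.path(out_dir, "power.csv"),
                       subject_ids = cohort$subject_id)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  truth_json <- list(
    planted_salience = sim$truth$planted_salience,
    planted_contrast = sim$truth$planted_contrast,
    latent_scores = sim$truth$latent_scores,
    generating_coefficients = as.list(sim$truth$generating_coefficients))
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(
    list(n_per_group = config$n_per_group, n_sources = config$n_sources,
         bands = config$bands, contrast_effect = config$contrast_effect,
         noise_sd = config$noise_sd, latent_sd = config$latent_sd,
         mri_per_group = config$mri_per_group, seed = config$seed,
         n_perm = n_perm, n_boot = n_boot, master_seed = seed),
    cfg_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tick("simulate")

  # 1. group differences in power
  a1 <- run("pls_group",
            run_pls(power, groups = cohort$group, n_perm = n_perm,
                    n_boot = n_boot, seed = stage_seed(seed, "pls_group")))
  write_pls_result(a1, file.path(out_dir, "analysis1_group"),
                   seed = stage_seed(seed, "pls_group"))
  tick("pls_group")

  # 2. power vs neurocognitive outcome (listwise complete cases)
  ycols <- .outcome_columns()
  keep2 <- stats::complete.cases(cohort[, ycols])
  a2 <- run("pls_neuro",
            run_pls(power[keep2, , drop = FALSE],
                    groups = cohort$group[keep2],
                    Y = as.matrix(cohort[keep2, ycols]),
                    n_perm = n_perm, n_boot = n_boot,
                    seed = stage_seed(seed, "pls_neuro")))
  a2$n_sources <- attr(power, "n_sources"); a2$bands <- attr(power, "bands")
  write_pls_result(a2, file.path(out_dir, "analysis2_neurocognitive"),
                   seed = stage_seed(seed, "pls_neuro"))
  tick("pls_neuro")

  # 3. power vs normalized intensities (structural subset)
  icols <- c("TI", "CGI", "CWI")
  keep3 <- stats::complete.cases(cohort[, icols])
  a3 <- run("pls_intensity",
            run_pls(power[keep3, , drop = FALSE],
                    groups = cohort$group[keep3],
                    Y = as.matrix(cohort[keep3, icols]),
                    n_perm = n_perm, n_boot = n_boot,
                    seed = stage_seed(seed, "pls_intensity")))
  a3$n_sources <- attr(power, "n_sources"); a3$bands <- attr(power, "bands")
  write_pls_result(a3, file.path(out_dir, "analysis3_intensity"),
                   seed = stage_seed(seed, "pls_intensity"))
  tick("pls_intensity")

  # 4. power vs TV-CGV ratio (structural subset)
  ratio <- tv_cgv_ratio(cohort$TV, cohort$CGV)
  keep4 <- !is.na(ratio)
  a4 <- run("pls_volume",
            run_pls(power[keep4, , drop = FALSE],
                    groups = cohort$group[keep4],
                    Y = matrix(ratio[keep4], ncol = 1,
                               dimnames = list(NULL, "TV_CGV")),
                    n_perm = n_perm, n_boot = n_boot,
                    seed = stage_seed(seed, "pls_volume")))
  a4$n_sources <- attr(power, "n_sources"); a4$bands <- attr(power, "bands")
  write_pls_result(a4, file.path(out_dir, "analysis4_volume"),
                   seed = stage_seed(seed, "pls_volume"))
  tick("pls_volume")

  # post-hoc: z-map correlations, brain-score/volume correlations,
  # tail-power associations, neonatal regressions
  posthoc_dir <- file.path(out_dir, "posthoc")
  dir.create(posthoc_dir, showWarnings = FALSE)
  z1 <- zmap(a1); z2 <- zmap(a2); z3 <- zmap(a3); z4 <- zmap(a4)
  zcor <- data.frame(
    comparison = c("intensity_vs_group", "volume_vs_neurocognitive"),
    r = c(correlate_zmaps(z3, z1), correlate_zmaps(z4, z2)))
  utils::write.csv(zcor, file.path(posthoc_dir, "zmap_correlations.csv"),
                   row.names = FALSE)

  scores1 <- a1$brain_scores[, 1L]
  volcor <- run("brainscore_volumes",
                correlate_scores_with_volumes(scores1, cohort$TV, cohort$CGV))
  utils::write.csv(volcor,
                   file.path(posthoc_dir, "brainscore_volume_correlations.csv"),
                   row.names = FALSE)

  tails <- run("tail_association",
               tail_power_association(z4, power, covariate = ratio,
                                      groups = cohort$group))
  tail_rows <- do.call(rbind, lapply(tails, function(tb)
    cbind(band = tb$band, skewness = tb$skewness, tail = tb$tail,
          tb$correlations)))
  utils::write.csv(tail_rows, file.path(posthoc_dir, "tail_associations.csv"),
                   row.names = FALSE)
  sel_rows <- do.call(rbind, lapply(tails, function(tb)
    data.frame(band = tb$band, source = tb$selected_sources)))
  utils::write.csv(sel_rows, file.path(posthoc_dir, "tail_selected_sources.csv"),
                   row.names = FALSE)

  reg <- list(TI = run("regression_TI", neonatal_regression(cohort, "TI")),
              TV_CGV = run("regression_TV_CGV",
                           neonatal_regression(cohort, "TV_CGV")))
  for (nm in names(reg)) {
    r <- reg[[nm]]
    utils::write.csv(
      rbind(r$coefficients,
            data.frame(term = c("F", "df1", "df2", "R2", "n"),
                       beta = c(r$F, r$df1, r$df2, r$r_squared, r$n),
                       p = NA_real_)),
      file.path(posthoc_dir, paste0("regression_", nm, ".csv")),
      row.names = FALSE)
  }
  tick("posthoc")

  files <- list.files(out_dir, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("megpls")),
    master_seed = seed,
    stage_seeds = as.list(vapply(c("cohort", "pls_group", "pls_neuro",
                                   "pls_intensity", "pls_volume"),
                                 function(s) stage_seed(seed, s), integer(1))),
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_perm = n_perm, n_boot = n_boot,
    availability = as.list(validation$availability),
    stage_wall_time_s = as.list(timings),
    files = setdiff(files, "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(power = power, cohort = cohort, truth = sim$truth,
                 validation = validation,
                 pls_group = a1, pls_neurocognitive = a2,
                 pls_intensity = a3, pls_volume = a4,
                 zmap_correlations = zcor,
                 brainscore_volume_correlations = volcor,
                 tail_associations = tails,
                 regressions = reg,
                 manifest = manifest, out_dir = out_dir))
}
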