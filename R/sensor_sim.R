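# Synthetic sensor-level recordings through the toy forward model.

#' Simulate a multichannel sensor recording
#'
#' Each source emits a sum of band-limited Gaussian noise processes with the
#' requested per-band standard deviations; the sensor data are the oriented
#' lead field applied to the source series plus white sensor noise. A
#' synthetic continuous head-localization trace (three fiducial coils) is
#' attached, optionally with a planted excursion for testing motion
#' rejection.
#'
#' @param leadfield A `lead_field` (see [make_toy_leadfield()]).
#' @param source_spectra Sources-by-bands matrix of per-band amplitudes
#'   (standard deviation of the band-limited source series, A*m).
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz (default 1200, a typical laboratory rate).
#' @param noise_sd Standard deviation of white sensor noise (T).
#' @param motion_trace_params Optional list with elements `excursion_mm`,
#'   `start_s`, `end_s`, and optionally `direction` (3-vector, default x)
#'   and `fiducials` (indices, default all three): a head displacement
#'   planted over the given time window.
#' @param seed Optional integer seed.
#' @param bands Band definition data frame matching `source_spectra` columns.
#' @return A [sensor_recording()] plus attribute `source_data` (the simulated
#'   sources-by-samples series) for verification.
#' @export
generate_sensor_recording <- function(leadfield, source_spectra, duration_s,
                                      fs = 1200, noise_sd = 0,
                                      motion_trace_params = NULL, seed = NULL,
                                      bands = canonical_bands()) {
  bands <- validate_bands(bands)
  source_spectra <- as.matrix(source_spectra)
  nsrc <- nrow(leadfield$source_positions)
  if (nrow(source_spectra) != nsrc || ncol(source_spectra) != nrow(bands))
    stop("`source_spectra` must be n_sources x n_bands")
  if (any(bands$hi >= fs / 2))
    stop("band edge at or above fs/2; increase `fs`")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  src <- matrix(0, nsrc, n)
  for (b in seq_len(nrow(bands))) {
    active <- which(source_spectra[, b] > 0)
    if (!length(active)) next
    h <- fir_band_coef(fs, bands$lo[b], bands$hi[b])
    for (s in active) {
      x <- apply_fir_zerophase(stats::rnorm(n), h)
      src[s, ] <- src[s, ] + x / stats::sd(x) * source_spectra[s, b]
    }
  }
  og <- oriented_gain(leadfield)
  data <- og$gain %*% src
  if (noise_sd > 0)
    data <- data + matrix(stats::rnorm(length(data), 0, noise_sd), nrow(data))

  # fiducial trace: nasion and left/right preauricular points, constant head
  # position unless an excursion is planted
  fid0 <- rbind(c(0, 90, -10), c(-72, 0, -30), c(72, 0, -30))
  hp <- array(rep(fid0, n), dim = c(3, 3, n))
  if (!is.null(motion_trace_params)) {
    mp <- motion_trace_params
    dir <- if (!is.null(mp$direction)) mp$direction else c(1, 0, 0)
    dir <- dir / sqrt(sum(dir^2))
    fids <- if (!is.null(mp$fiducials)) mp$fiducials else 1:3
    i0 <- max(1L, floor(mp$start_s * fs) + 1L)
    i1 <- min(n, ceiling(mp$end_s * fs))
    for (f in fids)
      hp[f, , i0:i1] <- hp[f, , i0:i1] + mp$excursion_mm * dir
  }
  rec <- sensor_recording(data, fs, head_position = hp)
  attr(rec, "source_data") <- src
  rec
}
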