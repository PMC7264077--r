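# From time series to relative band power: motion rejection, epoching,
# band filtering, compositional normalization.

#' Flag samples by head displacement
#'
#' A sample is retained iff the Euclidean displacement of *every* fiducial
#' coil from its per-recording median position is at most `threshold_mm`.
#'
#' @param rec A [sensor_recording()] with a head-position trace.
#' @param threshold_mm Displacement threshold in mm (default 5).
#' @return Logical vector of length `n_samples`; `TRUE` marks retained
#'   samples.
#' @export
reject_motion_segments <- function(rec, threshold_mm = 5) {
  if (!inherits(rec, "sensor_recording")) stop("`rec` must be a sensor_recording")
  hp <- rec$head_position
  if (is.null(hp))
    stop("recording has no head-position trace; motion masking cannot be skipped")
  n <- dim(hp)[3]
  keep <- rep(TRUE, n)
  for (f in 1:3) {
    med <- apply(hp[f, , , drop = FALSE], 2L, stats::median)
    disp <- sqrt(colSums((hp[f, , ] - med)^2))
    keep <- keep & (disp <= threshold_mm)
  }
  keep
}

#' Segment a recording into fixed-length epochs
#'
#' Contiguous, non-overlapping windows aligned to the start of each retained
#' run of samples; windows extending into rejected samples or past the end
#' of the recording are dropped.
#'
#' @param rec A [sensor_recording()], or a channels-by-samples matrix (then
#'   `fs` must be given).
#' @param mask Optional logical retained-sample mask (default: all retained).
#' @param epoch_s Epoch length in seconds (default 4).
#' @param fs Sampling rate, required when `rec` is a bare matrix.
#' @return An [epoch_set()].
#' @export
segment_epochs <- function(rec, mask = NULL, epoch_s = 4, fs = NULL) {
  if (inherits(rec, "sensor_recording")) {
    data <- rec$data; fs <- rec$fs
  } else {
    data <- as.matrix(rec)
    if (is.null(fs)) stop("`fs` must be supplied for a bare matrix")
  }
  n <- ncol(data)
  el <- epoch_s * fs
  if (abs(el - round(el)) > 1e-9) stop("epoch_s * fs must be an integer number of samples")
  el <- as.integer(round(el))
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n) stop("mask length must equal the number of samples")
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onsets <- integer(0)
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    k <- (r$lengths[i]) %/% el
    if (k > 0L) onsets <- c(onsets, starts[i] + el * (seq_len(k) - 1L))
  }
  if (!length(onsets))
    stop("no usable data: no complete ", epoch_s, " s epoch inside retained segments")
  out <- array(0, dim = c(length(onsets), nrow(data), el))
  for (e in seq_along(onsets))
    out[e, , ] <- data[, onsets[e]:(onsets[e] + el - 1L), drop = FALSE]
  epoch_set(out, fs)
}

#' Absolute band power per channel
#'
#' Each epoch and channel is band-pass filtered with a zero-phase FIR at
#' each band and the band power is the variance of the filtered series,
#' averaged over epochs. Band edges are half-open `[lo, hi)` by filter
#' design, so shared edges are not double counted.
#'
#' @param epochs An [epoch_set()].
#' @param bands Band definition data frame.
#' @return Channels-by-bands matrix of absolute power (signal units squared).
#' @export
band_power <- function(epochs, bands = canonical_bands()) {
  if (!inherits(epochs, "epoch_set")) stop("`epochs` must be an epoch_set")
  bands <- validate_bands(bands)
  fs <- epochs$fs
  if (any(bands$hi >= fs / 2))
    stop("band edge at or above Nyquist (", fs / 2, " Hz)")
  d <- dim(epochs$data)
  ne <- d[1]; nc <- d[2]; ns <- d[3]
  out <- matrix(0, nc, nrow(bands), dimnames = list(NULL, bands$name))
  for (b in seq_len(nrow(bands))) {
    h <- fir_band_coef(fs, bands$lo[b], bands$hi[b])
    H <- fir_zerophase_response(h, ns)
    acc <- matrix(0, ne, nc)
    for (e in seq_len(ne)) for (ch in seq_len(nc)) {
      y <- apply_fir_periodic(epochs$data[e, ch, ], H)
      acc[e, ch] <- stats::var(y)
    }
    out[, b] <- colMeans(acc)
  }
  out
}

#' Relative band power
#'
#' Divides the absolute power in each band by the summed absolute power over
#' all bands, per channel, giving a compositional (sum-to-one) quantity that
#' is invariant to global amplitude rescaling of the input signal (and hence
#' to source-depth bias in beamformer output).
#'
#' @param abs_power Channels-by-bands matrix (or a vector of per-band values
#'   for a single channel) of non-negative absolute powers.
#' @return Object of the same shape with rows summing to one.
#' @export
relative_power <- function(abs_power) {
  vec <- is.null(dim(abs_power))
  p <- if (vec) matrix(abs_power, nrow = 1L) else as.matrix(abs_power)
  if (any(p < 0)) stop("absolute power must be non-negative")
  tot <- rowSums(p)
  if (any(tot == 0))
    stop("all band powers are zero for channel(s) ",
         paste(which(tot == 0), collapse = ", "),
         ": relative power is undefined")
  out <- p / tot
  if (vec) drop(out) else out
}

# Filter every epoch/channel to one band (used for per-band beamforming).
# Epochs are treated as circular, matching band_power().
filter_epochs <- function(epochs, lo, hi) {
  if (!inherits(epochs, "epoch_set")) stop("`epochs` must be an epoch_set")
  h <- fir_band_coef(epochs$fs, lo, hi)
  d <- dim(epochs$data)
  H <- fir_zerophase_response(h, d[3])
  out <- epochs$data
  for (e in seq_len(d[1])) for (ch in seq_len(d[2]))
    out[e, ch, ] <- apply_fir_periodic(epochs$data[e, ch, ], H)
  epoch_set(out, epochs$fs)
}
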