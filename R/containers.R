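# Lightweight S3 containers shared across modules.

#' Construct a band-power matrix
#'
#' Subjects-by-features matrix of relative band power, features ordered
#' source-major (`s1_delta, s1_theta, ..., s2_delta, ...`). Values must be
#' non-negative and sum to one over the bands of each source, per subject.
#'
#' @param values Numeric matrix, subjects by `n_sources * nrow(bands)`.
#' @param n_sources Number of source locations.
#' @param bands Band definition data frame.
#' @param check If `TRUE` (default), validate the compositional constraint.
#' @return A `band_power_matrix` (a numeric matrix with attributes
#'   `n_sources` and `bands`).
#' @export
band_power_matrix <- function(values, n_sources, bands = canonical_bands(),
                              check = TRUE) {
  bands <- validate_bands(bands)
  values <- as.matrix(values)
  nb <- nrow(bands)
  if (ncol(values) != n_sources * nb)
    stop("expected ", n_sources * nb, " feature columns, got ", ncol(values))
  if (is.null(colnames(values)))
    colnames(values) <- feature_names(n_sources, bands)
  if (check) {
    if (any(values < 0) || any(values > 1))
      stop("relative power values must lie in [0, 1]")
    for (s in seq_len(n_sources)) {
      cols <- ((s - 1L) * nb + 1L):(s * nb)
      if (any(abs(rowSums(values[, cols, drop = FALSE]) - 1) > 1e-10))
        stop("band powers at source ", s, " do not sum to 1 within 1e-10")
    }
  }
  structure(values, n_sources = n_sources, bands = bands,
            class = c("band_power_matrix", "matrix", "array"))
}

#' @export
print.band_power_matrix <- function(x, ...) {
  cat("band_power_matrix:", nrow(x), "subjects x", ncol(x), "features (",
      attr(x, "n_sources"), "sources x", nrow(attr(x, "bands")), "bands )\n")
  invisible(x)
}

#' Construct a sensor recording
#'
#' @param data Channels-by-samples numeric matrix (sensor field values).
#' @param fs Sampling rate in Hz.
#' @param head_position Optional array `3 fiducials x 3 coordinates x samples`
#'   of continuous head-localization coil positions, in mm.
#' @return A `sensor_recording` list.
#' @export
sensor_recording <- function(data, fs, head_position = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("sensor data must be finite")
  if (fs <= 0) stop("`fs` must be positive")
  if (!is.null(head_position)) {
    d <- dim(head_position)
    if (length(d) != 3L || d[1] != 3L || d[2] != 3L || d[3] != ncol(data))
      stop("`head_position` must be a 3 x 3 x n_samples array")
  }
  structure(list(data = data, fs = fs, head_position = head_position),
            class = "sensor_recording")
}

#' Construct an epoch set
#'
#' @param data Array `epochs x channels x samples`.
#' @param fs Sampling rate in Hz.
#' @return An `epoch_set` list with the epoch length in seconds.
#' @export
epoch_set <- function(data, fs) {
  d <- dim(data)
  if (length(d) != 3L || d[1] < 1L) stop("`data` must be epochs x channels x samples, with at least one epoch")
  structure(list(data = data, fs = fs, epoch_s = d[3] / fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("epoch_set:", d[1], "epochs x", d[2], "channels x", d[3],
      "samples @", x$fs, "Hz\n")
  invisible(x)
}
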