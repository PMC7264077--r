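# Zero-phase FIR filtering.
#
# Band-pass filters are windowed-sinc FIR designs (signal::fir1, Hamming
# window, passband ripple well under 1%). Because the impulse response is
# symmetric (linear phase), a single convolution followed by group-delay
# compensation is exactly zero phase; edges are handled by point-symmetric
# reflection padding so that short epochs do not suffer filter transients.

# Transition width heuristic: narrow enough that the equivalent noise
# bandwidth stays within a few percent of (hi - lo), wide enough to keep
# filters shorter than typical 4 s epochs.
fir_transition_width <- function(lo, hi) {
  max(0.5, min(lo / 2, (hi - lo) / 4, 2))
}

fir_band_coef <- function(fs, lo, hi, n_taps = NULL, type = "pass") {
  nyq <- fs / 2
  if (hi >= nyq) stop("band edge ", hi, " Hz is at or above Nyquist (", nyq, " Hz)")
  if (is.null(n_taps)) {
    tw <- fir_transition_width(lo, hi)
    order <- ceiling(3.3 * fs / tw)
    if (order %% 2 == 1L) order <- order + 1L   # even order -> odd length, integer delay
    n_taps <- order + 1L
  }
  signal::fir1(n_taps - 1L, c(lo, hi) / nyq, type = type)
}

# Apply a symmetric odd-length FIR with zero phase via reflection padding.
apply_fir_zerophase <- function(x, h) {
  n <- length(x)
  m <- length(h)
  if (m %% 2 != 1L) stop("FIR length must be odd for integer group delay")
  d <- (m - 1L) / 2L
  if (d > n - 1L) {
    # cap the filter to what the signal can support (still odd length)
    m <- 2L * (n - 1L) + 1L
    mid <- (length(h) + 1L) / 2L
    h <- h[(mid - (m - 1L) / 2L):(mid + (m - 1L) / 2L)]
    d <- (m - 1L) / 2L
  }
  pad <- min(n - 1L, m)
  left  <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(left, x, right)
  y <- stats::convolve(xp, rev(h), type = "open")
  y[(pad + d + 1L):(pad + d + n)]
}

# Band-pass filter a vector with the default zero-phase FIR for [lo, hi).
fir_bandpass <- function(x, fs, lo, hi, n_taps = NULL) {
  h <- fir_band_coef(fs, lo, hi, n_taps = n_taps, type = "pass")
  apply_fir_zerophase(x, h)
}

# Zero-phase frequency response of a symmetric odd-length FIR at the n DFT
# bins of an epoch: H(2*pi*k/n), real because the group delay is removed.
fir_zerophase_response <- function(h, n) {
  m <- length(h)
  d <- (m - 1L) / 2L
  # delay-compensated impulse response wrapped onto the epoch length; its
  # DFT samples the continuous zero-phase response at the bin frequencies
  hw <- numeric(n)
  pos <- ((seq_len(m) - 1L - d) %% n) + 1L
  for (j in seq_len(m)) hw[pos[j]] <- hw[pos[j]] + h[j]
  Re(stats::fft(hw))
}

# Apply a zero-phase FIR to a fixed-length epoch under periodic extension:
# multiply the epoch's DFT by the filter's (real) zero-phase response. For
# stationary signals this estimates band variance without edge transients.
apply_fir_periodic <- function(x, H) {
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / length(x)
}

#' Remove power-line noise with a zero-phase FIR notch
#'
#' Band-stop filter centred on the line frequency. On synthetic recordings
#' without line interference this step is inert; it is provided so that the
#' preprocessing chain matches what is applied to laboratory recordings.
#'
#' @param x Numeric vector, or a channels-by-samples matrix.
#' @param fs Sampling rate in Hz.
#' @param freq Line frequency in Hz (default 60).
#' @param width Half-width of the stop band in Hz (default 2).
#' @return Filtered object of the same shape.
#' @export
notch_line_noise <- function(x, fs, freq = 60, width = 2) {
  if (freq + width >= fs / 2) stop("notch band is at or above Nyquist")
  h <- fir_band_coef(fs, freq - width, freq + width, type = "stop")
  if (is.matrix(x)) {
    t(apply(x, 1L, apply_fir_zerophase, h = h))
  } else {
    apply_fir_zerophase(x, h)
  }
}
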