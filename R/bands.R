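#' Canonical frequency bands
#'
#' The five canonical bands used throughout the pipeline: delta 1--4 Hz,
#' theta 4--8 Hz, alpha 8--12 Hz, beta 12--25 Hz, gamma 25--55 Hz. Band
#' edges are treated as half-open `[lo, hi)` so that shared edges
#' (4, 8, 12, 25 Hz) are not counted twice.
#'
#' @return A data frame with columns `name`, `lo` and `hi` (Hz), one row per
#'   band, in fixed spectral order.
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo   = c(1, 4, 8, 12, 25),
    hi   = c(4, 8, 12, 25, 55),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands) {
  if (!is.data.frame(bands) || !all(c("name", "lo", "hi") %in% names(bands)))
    stop("`bands` must be a data frame with columns name, lo, hi")
  if (nrow(bands) < 1L) stop("`bands` must contain at least one band")
  if (any(bands$lo <= 0) || any(bands$hi <= bands$lo))
    stop("band edges must satisfy 0 < lo < hi")
  if (anyDuplicated(bands$name)) stop("band names must be unique")
  bands
}

#' Feature names for a source-by-band power matrix
#'
#' Features are ordered source-major: all bands of source 1, then all bands
#' of source 2, and so on. Column `s<idx>_<bandname>` holds the relative
#' power of band `<bandname>` at source `<idx>`.
#'
#' @param n_sources Number of source locations.
#' @param bands Band definition data frame (see [canonical_bands()]).
#' @return Character vector of length `n_sources * nrow(bands)`.
#' @export
feature_names <- function(n_sources, bands = canonical_bands()) {
  bands <- validate_bands(bands)
  paste0("s", rep(seq_len(n_sources), each = nrow(bands)), "_",
         rep(bands$name, n_sources))
}

#' Feature index of a source-by-band matrix
#'
#' @param n_sources Number of source locations.
#' @param bands Band definition data frame.
#' @return Data frame with columns `feature`, `source`, `band` aligned with
#'   the column order produced by [feature_names()].
#' @export
feature_index <- function(n_sources, bands = canonical_bands()) {
  bands <- validate_bands(bands)
  data.frame(
    feature = feature_names(n_sources, bands),
    source  = rep(seq_len(n_sources), each = nrow(bands)),
    band    = rep(bands$name, n_sources),
    stringsAsFactors = FALSE
  )
}
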