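# Linearly constrained minimum-variance (LCMV) source projection.
#
# Weights are computed per frequency band from a covariance of band-filtered
# epochs with diagonal loading. The scalar (optimal-orientation) variant is
# used: at each source the orientation maximizing beamformer output power is
# selected among orientations with non-vanishing lead field (the radial
# direction is magnetically silent in a spherical conductor and is excluded
# numerically), then the classic unit-gain minimum-variance weights are
# formed for the oriented lead-field column.

#' Pooled, regularized sensor covariance
#'
#' Covariance pooled over epochs after per-epoch mean removal, with diagonal
#' loading equal to `reg_fraction` times the mean sensor power (mean of the
#' covariance diagonal).
#'
#' @param epochs An [epoch_set()].
#' @param reg_fraction Diagonal loading as a fraction of mean sensor power
#'   (default 0.05, i.e. 5%).
#' @return A `sensor_covariance` list with elements `matrix` (channels by
#'   channels) and `regularization`.
#' @export
sensor_covariance <- function(epochs, reg_fraction = 0.05) {
  if (!inherits(epochs, "epoch_set")) stop("`epochs` must be an epoch_set")
  if (reg_fraction < 0) stop("`reg_fraction` must be non-negative")
  d <- dim(epochs$data)
  ne <- d[1]; nc <- d[2]; ns <- d[3]
  if (!all(is.finite(epochs$data))) stop("non-finite values in epoch data")
  if (ne * ns <= nc)
    warning("fewer samples (", ne * ns, ") than recommended for ", nc,
            " channels; covariance estimate will be poor")
  C <- matrix(0, nc, nc)
  for (e in seq_len(ne)) {
    X <- epochs$data[e, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = nc)
    X <- X - rowMeans(X)
    C <- C + tcrossprod(X)
  }
  C <- C / (ne * ns)
  C <- (C + t(C)) / 2
  C_reg <- C + diag(reg_fraction * mean(diag(C)), nc)
  ev_min <- min(eigen(C_reg, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-12 * mean(diag(C_reg)))
    stop("regularized covariance is singular (min eigenvalue ", ev_min,
         "); data are rank deficient - increase reg_fraction")
  structure(list(matrix = C_reg, regularization = reg_fraction),
            class = "sensor_covariance")
}

#' LCMV spatial-filter weights
#'
#' For each source, the dipole orientation is chosen as the unit vector
#' maximizing beamformer output power (the eigenvector of the smallest
#' eigenvalue of \eqn{L^T C^{-1} L} within the magnetically visible
#' subspace), and the weights are \eqn{w = C^{-1} l / (l^T C^{-1} l)} for
#' the oriented lead-field column \eqn{l}, which enforces unit gain at the
#' target location.
#'
#' @param leadfield A `lead_field`.
#' @param cov A [sensor_covariance()] built from data filtered to the band
#'   the filter is intended for.
#' @param band Optional one-row band definition recorded in the output.
#' @return A `spatial_filter` list: `weights` (sources by channels),
#'   `orientation` (sources by 3), `band`.
#' @export
lcmv_weights <- function(leadfield, cov, band = NULL) {
  if (!inherits(cov, "sensor_covariance")) stop("`cov` must be a sensor_covariance")
  C <- cov$matrix
  Cinv <- tryCatch(chol2inv(chol(C)),
                   error = function(e) stop("singular regularized covariance: ",
                                            conditionMessage(e)))
  nsrc <- nrow(leadfield$source_positions)
  nsen <- nrow(leadfield$sensor_positions)
  if (ncol(C) != nsen) stop("covariance dimension does not match the sensor count")
  W <- matrix(0, nsrc, nsen)
  ori <- matrix(0, nsrc, 3L)
  for (s in seq_len(nsrc)) {
    L <- t(leadfield$gain[s, , ])            # sensors x 3
    sv <- svd(L)
    visible <- sv$d > 1e-8 * sv$d[1]
    V <- sv$v[, visible, drop = FALSE]       # visible orientation subspace
    A <- crossprod(L, Cinv %*% L)            # 3 x 3
    B <- crossprod(V, A %*% V)
    eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
    eta <- as.vector(V %*% eg$vectors[, ncol(B)])  # smallest eigenvalue
    eta <- eta / sqrt(sum(eta^2))
    if (eta[which.max(abs(eta))] < 0) eta <- -eta
    l <- as.vector(L %*% eta)
    Cl <- Cinv %*% l
    denom <- as.numeric(crossprod(l, Cl))
    if (!is.finite(denom) || denom <= 0)
      stop("degenerate lead field at source ", s)
    W[s, ] <- Cl / denom
    ori[s, ] <- eta
  }
  structure(list(weights = W, orientation = ori, band = band),
            class = "spatial_filter")
}

#' Project sensor epochs to source space
#'
#' @param filter A [lcmv_weights()] spatial filter.
#' @param epochs An [epoch_set()] of sensor data.
#' @return An [epoch_set()] of source series (epochs x sources x samples).
#' @export
project_sources <- function(filter, epochs) {
  if (!inherits(filter, "spatial_filter")) stop("`filter` must be a spatial_filter")
  if (!inherits(epochs, "epoch_set")) stop("`epochs` must be an epoch_set")
  d <- dim(epochs$data)
  if (ncol(filter$weights) != d[2])
    stop("filter expects ", ncol(filter$weights), " channels, epochs have ", d[2])
  nsrc <- nrow(filter$weights)
  out <- array(0, dim = c(d[1], nsrc, d[3]))
  for (e in seq_len(d[1]))
    out[e, , ] <- filter$weights %*% epochs$data[e, , , drop = TRUE]
  epoch_set(out, epochs$fs)
}

#' Per-band LCMV source power
#'
#' The full sensor-to-source spectral chain for one subject: for each band,
#' filter the epochs, estimate the regularized covariance, compute LCMV
#' weights, project to source space and take the source variance averaged
#' over epochs; finally normalize to relative power per source.
#'
#' @param leadfield A `lead_field`.
#' @param epochs An [epoch_set()] of broadband sensor data.
#' @param bands Band definition data frame.
#' @param reg_fraction Diagonal loading fraction (default 0.05).
#' @return List with `abs_power` and `rel_power` (sources by bands) and
#'   `filters` (one `spatial_filter` per band).
#' @export
beamformer_band_power <- function(leadfield, epochs, bands = canonical_bands(),
                                  reg_fraction = 0.05) {
  bands <- validate_bands(bands)
  nsrc <- nrow(leadfield$source_positions)
  absp <- matrix(0, nsrc, nrow(bands), dimnames = list(NULL, bands$name))
  filters <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    eb <- filter_epochs(epochs, bands$lo[b], bands$hi[b])
    cv <- sensor_covariance(eb, reg_fraction)
    flt <- lcmv_weights(leadfield, cv, band = bands[b, ])
    src <- project_sources(flt, eb)
    d <- dim(src$data)
    v <- matrix(0, d[1], d[2])
    for (e in seq_len(d[1]))
      v[e, ] <- apply(src$data[e, , , drop = TRUE], 1L, stats::var)
    absp[, b] <- colMeans(v)
    filters[[b]] <- flt
  }
  list(abs_power = absp, rel_power = relative_power(absp), filters = filters)
}
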