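# Spherical-conductor forward model.
#
# The magnetic field of a current dipole inside a homogeneous conducting
# sphere has a closed form (Sarvas' formula). It preserves the property that
# radial dipoles are magnetically silent, which downstream beamformer code
# relies on when choosing source orientations. Positions are kept in mm at
# the interface and converted to metres internally; gains are in
# T per (A*m), for point magnetometers measuring the field component along
# their orientation.

.sarvas_field <- function(r0, q, r) {
  # r0, q, r: 3-vectors (source position, moment, sensor position), SI units
  mu0 <- 4 * pi * 1e-7
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2))
  rn <- sqrt(sum(r^2))
  F <- a * (rn * a + rn^2 - sum(r0 * r))
  gradF <- (a^2 / rn + sum(a_vec * r) / a + 2 * a + 2 * rn) * r -
    (a + 2 * rn + sum(a_vec * r) / a) * r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  mu0 / (4 * pi * F^2) * (F * qxr0 - sum(qxr0 * r) * gradF)
}

# Evenly distributed points on a sphere (Fibonacci lattice).
.fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build a toy spherical-head lead field
#'
#' Sources are laid out on a regular cubic grid strictly inside a conducting
#' sphere centred at the origin; sensors are point magnetometers on a
#' concentric shell outside the sphere, oriented radially. The gain of each
#' source is the closed-form magnetic field of a current dipole in a
#' homogeneous conducting sphere, evaluated for unit moments along the three
#' coordinate axes.
#'
#' @param grid_spacing_mm Source grid spacing in mm.
#' @param n_sensors Number of sensors.
#' @param sphere_radius_mm Conductor radius in mm. Sources are kept within
#'   85% of this radius; sensors sit 20% outside it.
#' @return A `lead_field` list: `gain` (array sources x 3 orientations x
#'   sensors, T per A*m), `source_positions` (mm), `sensor_positions` and
#'   `sensor_orientations`.
#' @export
make_toy_leadfield <- function(grid_spacing_mm = 20, n_sensors = 64,
                               sphere_radius_mm = 90) {
  if (grid_spacing_mm <= 0 || sphere_radius_mm <= 0 || n_sensors < 1)
    stop("grid spacing, sphere radius and sensor count must be positive")
  rmax <- 0.85 * sphere_radius_mm
  g <- seq(-rmax, rmax, by = grid_spacing_mm)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  keep <- sqrt(rowSums(pts^2)) <= rmax & sqrt(rowSums(pts^2)) > 1e-9
  src <- pts[keep, , drop = FALSE]
  if (nrow(src) < 1L) stop("no grid points inside the sphere; decrease grid_spacing_mm")
  sens <- .fibonacci_sphere(n_sensors, 1.2 * sphere_radius_mm)
  orient <- sens / sqrt(rowSums(sens^2))
  lead_field(src, sens, orient, sphere_radius_mm)
}

#' Assemble a lead field from explicit geometry
#'
#' @param source_positions Sources-by-3 matrix, mm, head-centred; every
#'   source must lie strictly inside the sphere and away from its centre.
#' @param sensor_positions Sensors-by-3 matrix, mm, outside the sphere.
#' @param sensor_orientations Sensors-by-3 matrix of unit normals.
#' @param sphere_radius_mm Conductor radius in mm.
#' @return A `lead_field` list (see [make_toy_leadfield()]).
#' @export
lead_field <- function(source_positions, sensor_positions,
                       sensor_orientations, sphere_radius_mm) {
  source_positions <- as.matrix(source_positions)
  sensor_positions <- as.matrix(sensor_positions)
  sensor_orientations <- as.matrix(sensor_orientations)
  rs <- sqrt(rowSums(source_positions^2))
  if (any(rs < 1e-9))
    stop("source at the sphere centre: the spherical forward model is singular there")
  if (any(rs >= sphere_radius_mm))
    stop("all sources must lie strictly inside the sphere")
  if (any(sqrt(rowSums(sensor_positions^2)) <= sphere_radius_mm))
    stop("all sensors must lie outside the sphere")
  nsrc <- nrow(source_positions)
  nsen <- nrow(sensor_positions)
  gain <- array(0, dim = c(nsrc, 3L, nsen))
  for (s in seq_len(nsrc)) {
    r0 <- source_positions[s, ] * 1e-3
    for (o in 1:3) {
      q <- c(0, 0, 0); q[o] <- 1
      for (m in seq_len(nsen)) {
        B <- .sarvas_field(r0, q, sensor_positions[m, ] * 1e-3)
        gain[s, o, m] <- sum(B * sensor_orientations[m, ])
      }
    }
  }
  if (!all(is.finite(gain))) stop("non-finite gain; check geometry")
  structure(list(gain = gain,
                 source_positions = source_positions,
                 sensor_positions = sensor_positions,
                 sensor_orientations = sensor_orientations,
                 sphere_radius_mm = sphere_radius_mm),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat("lead_field:", nrow(x$source_positions), "sources,",
      nrow(x$sensor_positions), "sensors, sphere radius",
      x$sphere_radius_mm, "mm\n")
  invisible(x)
}

# Unit vector tangential to the sphere at a source (deterministic choice).
.tangential_orientation <- function(pos) {
  z <- c(0, 0, 1)
  t1 <- c(pos[2] * z[3] - pos[3] * z[2],
          pos[3] * z[1] - pos[1] * z[3],
          pos[1] * z[2] - pos[2] * z[1])
  if (sqrt(sum(t1^2)) < 1e-9 * sqrt(sum(pos^2))) {
    x <- c(1, 0, 0)
    t1 <- c(pos[2] * x[3] - pos[3] * x[2],
            pos[3] * x[1] - pos[1] * x[3],
            pos[1] * x[2] - pos[2] * x[1])
  }
  t1 / sqrt(sum(t1^2))
}

# Sensors-by-sources gain for fixed (tangential) orientations.
oriented_gain <- function(leadfield, orientations = NULL) {
  nsrc <- nrow(leadfield$source_positions)
  nsen <- nrow(leadfield$sensor_positions)
  if (is.null(orientations)) {
    orientations <- t(vapply(seq_len(nsrc), function(s)
      .tangential_orientation(leadfield$source_positions[s, ]), numeric(3)))
  }
  G <- matrix(0, nsen, nsrc)
  for (s in seq_len(nsrc))
    G[, s] <- t(leadfield$gain[s, , ]) %*% orientations[s, ]
  list(gain = G, orientations = orientations)
}
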