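#' Current dipole source
#'
#' @param position numeric length-3, meters.
#' @param moment numeric length-3, A*m.
#' @param label optional string.
#' @return object of class `dipole_source`.
#' @export
dipole_source <- function(position, moment, label = NULL) {
  position <- as.numeric(position); moment <- as.numeric(moment)
  stopifnot(length(position) == 3, length(moment) == 3,
            all(is.finite(position)), all(is.finite(moment)))
  structure(list(position = position, moment = moment, label = label),
            class = "dipole_source")
}

MU0_OVER_4PI <- 1e-7  # T m / (A m)

# Magnetic field of a current dipole in a homogeneous conducting sphere
# (closed-form spherical-conductor solution). Vectorized over field points:
# `points` is an N x 3 matrix; returns an N x 3 matrix of B in tesla per
# the given moment (A*m). Valid outside the conductor; radial dipole
# moments are magnetically silent.
sarvas_field <- function(points, q_pos, q_mom, sphere) {
  points <- matrix(as.numeric(points), ncol = 3)
  r <- sweep(points, 2, sphere$center)        # field points rel. center
  r0 <- as.numeric(q_pos) - sphere$center     # dipole rel. center
  q <- as.numeric(q_mom)
  a_vec <- sweep(r, 2, r0)                    # r - r0
  a <- sqrt(rowSums(a_vec^2))
  rn <- sqrt(rowSums(r^2))
  if (any(a < 1e-12))
    stop("singular geometry: field point coincides with the dipole",
         call. = FALSE)
  adotr <- a_vec[, 1] * r[, 1] + a_vec[, 2] * r[, 2] + a_vec[, 3] * r[, 3]
  r0dotr <- r[, 1] * r0[1] + r[, 2] * r0[2] + r[, 3] * r0[3]
  Fg <- a * (rn * a + rn^2 - r0dotr)
  if (any(abs(Fg) < 1e-18))
    stop("singular geometry: field point on the dipole's radial line",
         call. = FALSE)
  c1 <- a^2 / rn + adotr / a + 2 * a + 2 * rn
  c2 <- a + 2 * rn + adotr / a
  gradF <- r * c1 - matrix(r0, nrow(r), 3, byrow = TRUE) * c2
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  qxr0dotr <- r[, 1] * qxr0[1] + r[, 2] * qxr0[2] + r[, 3] * qxr0[3]
  B <- (matrix(qxr0, nrow(r), 3, byrow = TRUE) * Fg - gradF * qxr0dotr) *
    (MU0_OVER_4PI / Fg^2)
  B
}

#' Magnetometer response to a current dipole
#'
#' Projection of the spherical-conductor dipole field onto a point
#' magnetometer's field axis. Linear in the dipole moment; radial moments
#' give exactly zero.
#'
#' @param dipole a [dipole_source()].
#' @param sensor_position numeric length-3, meters.
#' @param sensor_axis unit 3-vector, the field-sensitive axis.
#' @param sphere a [sphere_model()].
#' @return field projection in tesla.
#' @export
dipole_field_magnetometer <- function(dipole, sensor_position, sensor_axis,
                                      sphere) {
  B <- sarvas_field(matrix(sensor_position, 1), dipole$position,
                    dipole$moment, sphere)
  sum(B[1, ] * sensor_axis)
}

#' Planar-gradiometer response to a current dipole
#'
#' Two-point finite difference of the coil-normal field component along the
#' channel's differencing axis at the physical baseline, matching the
#' construction of real planar gradiometers:
#' (B(p + d/2 a) - B(p - d/2 a)) . n / d, units T/m.
#'
#' @param dipole a [dipole_source()].
#' @param channel one row of a `sensor_array`'s channel table (a list or
#'   single-row data frame with position, orientation `o*` = differencing
#'   axis, normal `n*` = field axis, `baseline`).
#' @param sphere a [sphere_model()].
#' @return gradient response in T/m.
#' @export
dipole_response_gradiometer <- function(dipole, channel, sphere) {
  if (!is.null(channel$kind) && channel$kind != "planar_gradiometer")
    stop("channel is not a planar gradiometer", call. = FALSE)
  p <- c(channel$x, channel$y, channel$z)
  axis <- c(channel$ox, channel$oy, channel$oz)
  nrm <- c(channel$nx, channel$ny, channel$nz)
  d <- channel$baseline
  pts <- rbind(p + d / 2 * axis, p - d / 2 * axis)
  B <- sarvas_field(pts, dipole$position, dipole$moment, sphere)
  (sum(B[1, ] * nrm) - sum(B[2, ] * nrm)) / d
}

# Responses of every channel of `array` to one dipole. Returns an M-vector
# in channel units (T for magnetometers, T/m for gradiometers).
channel_responses <- function(array, q_pos, q_mom, sphere) {
  ch <- array$channels
  out <- numeric(nrow(ch))
  mg <- which(ch$kind == "magnetometer")
  gr <- which(ch$kind == "planar_gradiometer")
  if (length(mg)) {
    pts <- as.matrix(ch[mg, c("x", "y", "z")])
    B <- sarvas_field(pts, q_pos, q_mom, sphere)
    out[mg] <- rowSums(B * as.matrix(ch[mg, c("ox", "oy", "oz")]))
  }
  if (length(gr)) {
    p <- as.matrix(ch[gr, c("x", "y", "z")])
    axis <- as.matrix(ch[gr, c("ox", "oy", "oz")])
    nrm <- as.matrix(ch[gr, c("nx", "ny", "nz")])
    d <- ch$baseline[gr]
    Bp <- sarvas_field(p + axis * (d / 2), q_pos, q_mom, sphere)
    Bm <- sarvas_field(p - axis * (d / 2), q_pos, q_mom, sphere)
    out[gr] <- (rowSums(Bp * nrm) - rowSums(Bm * nrm)) / d
  }
  out
}

#' Sensor pattern of a set of dipoles
#'
#' Superposed channel responses of one or more dipoles (rows of `positions`
#' and `moments`); the spatial topography multiplying a shared source time
#' course.
#'
#' @param array a `sensor_array`.
#' @param positions n x 3 matrix, meters.
#' @param moments n x 3 matrix, A*m.
#' @param sphere a [sphere_model()].
#' @return numeric M-vector in channel units per the given total moment.
#' @export
dipole_pattern <- function(array, positions, moments, sphere) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  moments <- matrix(as.numeric(moments), ncol = 3)
  stopifnot(nrow(positions) == nrow(moments))
  out <- numeric(n_channels(array))
  for (i in seq_len(nrow(positions)))
    out <- out + channel_responses(array, positions[i, ], moments[i, ], sphere)
  out
}

#' Build the lead field of a regional source set
#'
#' Assembles the M x P matrix whose column j holds the response of every
#' channel to a unit (1 A*m) dipole along one tangential basis vector of
#' one source location; P = 2 per location. Row order is the channel order
#' of `array`; column order is (e_theta, e_phi) per location in the order
#' of `sources`.
#'
#' @param sources a `source_set`.
#' @param array a `sensor_array`.
#' @param sphere a [sphere_model()]; defaults to the source set's sphere.
#' @return object of class `lead_field` with fields `matrix`,
#'   `row_channels`, `col_components` (data frame label/component),
#'   `sphere`, `units`.
#' @export
build_leadfield <- function(sources, array, sphere = sources$sphere) {
  loc <- sources$locations
  if (nrow(loc) < 1L || n_channels(array) < 1L)
    stop("sources and array must be non-empty", call. = FALSE)
  P <- 2L * nrow(loc)
  L <- matrix(0, n_channels(array), P)
  comp <- data.frame(label = rep(loc$label, each = 2L),
                     component = rep(c("e_theta", "e_phi"), nrow(loc)),
                     stringsAsFactors = FALSE)
  for (j in seq_len(nrow(loc))) {
    p <- c(loc$x[j], loc$y[j], loc$z[j])
    L[, 2 * j - 1] <- channel_responses(array, p,
                                        c(loc$e1x[j], loc$e1y[j], loc$e1z[j]),
                                        sphere)
    L[, 2 * j] <- channel_responses(array, p,
                                    c(loc$e2x[j], loc$e2y[j], loc$e2z[j]),
                                    sphere)
  }
  structure(list(matrix = L, row_channels = array$channels$name,
                 col_components = comp, sphere = sphere,
                 units = "T (or T/m) per A*m"),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d channels x %d components, %s\n",
              nrow(x$matrix), ncol(x$matrix), x$units))
  invisible(x)
}
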