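#' Spherical head model
#'
#' The conductor model used throughout: a homogeneous sphere characterized
#' only by its center (the dipole field outside a spherical conductor does
#' not depend on the sphere radius). All coordinates are in meters, in a
#' right-handed head frame (x right, y anterior, z superior).
#'
#' @param center numeric length-3, sphere center in meters.
#' @return An object of class `sphere_model`.
#' @export
sphere_model <- function(center = c(0, 0, 0)) {
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("sphere center must be a finite 3-vector", call. = FALSE)
  structure(list(center = center), class = "sphere_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf("<sphere_model> center = (%g, %g, %g) m\n",
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

#' Tangential basis at a source position
#'
#' Returns the two spherical-coordinate tangential unit vectors (e_theta,
#' e_phi) at `position`, taken about the sphere center with the +z axis as
#' pole. Both are orthonormal and orthogonal to the radial direction. At the
#' pole (radial direction parallel to z) the convention degenerates and the
#' basis falls back to (x-hat, y-hat).
#'
#' @param position numeric length-3, meters.
#' @param sphere a [sphere_model()].
#' @return list with unit 3-vectors `e_theta` and `e_phi`.
#' @export
tangential_basis <- function(position, sphere) {
  r <- as.numeric(position) - sphere$center
  rn <- vnorm(r)
  if (rn < 1e-12)
    stop("degenerate geometry: position coincides with the sphere center",
         call. = FALSE)
  rho <- sqrt(r[1]^2 + r[2]^2)
  if (rho < 1e-9 * rn) {
    # polar degeneracy: any tangent pair works, fix (x, y)
    return(list(e_theta = c(1, 0, 0), e_phi = c(0, 1, 0)))
  }
  cph <- r[1] / rho; sph <- r[2] / rho
  cth <- r[3] / rn;  sth <- rho / rn
  list(e_theta = c(cth * cph, cth * sph, -sth),
       e_phi   = c(-sph, cph, 0))
}

#' Synthetic whole-head MEG helmet
#'
#' Builds a sensor array emulating a 306-channel triple-sensor MEG system:
#' `n_sites` sensor sites quasi-uniformly distributed (Fibonacci lattice)
#' over a spherical cap, each carrying one magnetometer with a radial field
#' axis and two planar gradiometers differencing the radial field component
#' along orthogonal tangential axes. Channel order is (magnetometer,
#' gradiometer A, gradiometer B) per site and is the canonical row order of
#' recordings and lead fields.
#'
#' Default noise SDs are 2e-13 T (200 fT) for magnetometers and 5e-12 T/m
#' (50 fT/cm) for gradiometers.
#'
#' @param n_sites number of sensor sites (306-channel default: 102).
#' @param helmet_radius radius of the sensor shell, meters.
#' @param coverage_angle half-angle of the spherical cap, radians.
#' @param seed integer recorded in the array metadata; the layout is fully
#'   deterministic.
#' @param mag_noise_sd,grad_noise_sd per-channel noise SD, T and T/m.
#' @param grad_baseline planar-gradiometer baseline, meters.
#' @return An object of class `sensor_array`.
#' @export
make_synthetic_helmet <- function(n_sites = 102L, helmet_radius = 0.12,
                                  coverage_angle = 2.2, seed = 1L,
                                  mag_noise_sd = 2e-13,
                                  grad_noise_sd = 5e-12,
                                  grad_baseline = 0.0168) {
  if (n_sites < 1L) stop("n_sites must be positive", call. = FALSE)
  if (helmet_radius <= 0) stop("helmet_radius must be positive", call. = FALSE)
  sph <- sphere_model()
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_sites)
  z <- 1 - (1 - cos(coverage_angle)) * (i - 0.5) / n_sites
  phi <- i * golden
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- helmet_radius * cbind(rho * cos(phi), rho * sin(phi), z)

  rows <- vector("list", 3L * n_sites)
  for (k in i) {
    p <- pos[k, ]
    rad <- unit(p)
    tb <- tangential_basis(p, sph)
    rows[[3 * k - 2]] <- data.frame(
      name = sprintf("MAG%04d", k), kind = "magnetometer",
      x = p[1], y = p[2], z = p[3],
      ox = rad[1], oy = rad[2], oz = rad[3],
      nx = rad[1], ny = rad[2], nz = rad[3],
      noise_sd = mag_noise_sd, baseline = NA_real_,
      stringsAsFactors = FALSE)
    rows[[3 * k - 1]] <- data.frame(
      name = sprintf("GRD%04dA", k), kind = "planar_gradiometer",
      x = p[1], y = p[2], z = p[3],
      ox = tb$e_theta[1], oy = tb$e_theta[2], oz = tb$e_theta[3],
      nx = rad[1], ny = rad[2], nz = rad[3],
      noise_sd = grad_noise_sd, baseline = grad_baseline,
      stringsAsFactors = FALSE)
    rows[[3 * k]] <- data.frame(
      name = sprintf("GRD%04dB", k), kind = "planar_gradiometer",
      x = p[1], y = p[2], z = p[3],
      ox = tb$e_phi[1], oy = tb$e_phi[2], oz = tb$e_phi[3],
      nx = rad[1], ny = rad[2], nz = rad[3],
      noise_sd = grad_noise_sd, baseline = grad_baseline,
      stringsAsFactors = FALSE)
  }
  sensor_array(do.call(rbind, rows), frame = "head",
               meta = list(seed = seed, helmet_radius = helmet_radius,
                           coverage_angle = coverage_angle))
}

#' Sensor array constructor
#'
#' @param channels data frame with columns `name`, `kind`
#'   ("magnetometer"/"planar_gradiometer"), position `x,y,z` (m),
#'   orientation `ox,oy,oz` (field axis for magnetometers, differencing
#'   axis for gradiometers), coil normal `nx,ny,nz` (field axis measured;
#'   radial for helmet gradiometers), `noise_sd` (T or T/m), `baseline`
#'   (m, gradiometers only).
#' @param frame coordinate-frame label.
#' @param meta optional list of provenance metadata.
#' @return object of class `sensor_array`.
#' @export
sensor_array <- function(channels, frame = "head", meta = list()) {
  stopifnot(is.data.frame(channels))
  needed <- c("name", "kind", "x", "y", "z", "ox", "oy", "oz",
              "nx", "ny", "nz", "noise_sd", "baseline")
  if (!all(needed %in% names(channels)))
    stop("channels is missing columns: ",
         paste(setdiff(needed, names(channels)), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(channels$name))
    stop("channel names must be unique", call. = FALSE)
  if (!all(channels$kind %in% c("magnetometer", "planar_gradiometer")))
    stop("unknown channel kind", call. = FALSE)
  if (!all(channels$noise_sd > 0))
    stop("noise_sd must be positive for every channel", call. = FALSE)
  onorm <- sqrt(channels$ox^2 + channels$oy^2 + channels$oz^2)
  if (any(abs(onorm - 1) > 1e-6))
    stop("channel orientations must be unit vectors", call. = FALSE)
  gr <- channels$kind == "planar_gradiometer"
  if (any(gr) && !all(channels$baseline[gr] > 0))
    stop("gradiometer baselines must be positive", call. = FALSE)
  rownames(channels) <- NULL
  structure(list(channels = channels, frame = frame, meta = meta),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  tab <- table(x$channels$kind)
  cat(sprintf("<sensor_array> %d channels (%s), frame '%s'\n",
              nrow(x$channels),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              x$frame))
  invisible(x)
}

n_channels <- function(array) nrow(array$channels)

channel_positions <- function(array) {
  as.matrix(array$channels[, c("x", "y", "z")])
}

#' Select a channel subset
#'
#' @param array a `sensor_array`.
#' @param kind `"all"`, `"magnetometer"` or `"planar_gradiometer"`, or a
#'   character vector of channel names.
#' @return a `sensor_array` restricted to the selection, original order kept.
#' @export
subset_channels <- function(array, kind = "all") {
  ch <- array$channels
  keep <- if (identical(kind, "all")) rep(TRUE, nrow(ch))
          else if (all(kind %in% c("magnetometer", "planar_gradiometer")))
            ch$kind %in% kind
          else ch$name %in% kind
  if (!any(keep)) stop("channel subset is empty", call. = FALSE)
  sensor_array(ch[keep, , drop = FALSE], frame = array$frame, meta = array$meta)
}

#' Regional source set constructor
#'
#' Attaches a tangential basis (e_theta, e_phi about the sphere center) to
#' each labeled location. For MEG each location carries two tangential
#' source components, so the component count is twice the location count.
#'
#' @param labels character vector of unique labels.
#' @param positions numeric matrix (n x 3), meters.
#' @param sphere a [sphere_model()].
#' @return object of class `source_set`.
#' @export
regional_source_set <- function(labels, positions, sphere) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(labels) == nrow(positions))
  if (anyDuplicated(labels)) stop("source labels must be unique", call. = FALSE)
  loc <- vector("list", length(labels))
  for (j in seq_along(labels)) {
    tb <- tangential_basis(positions[j, ], sphere)
    loc[[j]] <- data.frame(
      label = labels[j],
      x = positions[j, 1], y = positions[j, 2], z = positions[j, 3],
      e1x = tb$e_theta[1], e1y = tb$e_theta[2], e1z = tb$e_theta[3],
      e2x = tb$e_phi[1], e2y = tb$e_phi[2], e2z = tb$e_phi[3],
      stringsAsFactors = FALSE)
  }
  structure(list(locations = do.call(rbind, loc), sphere = sphere),
            class = "source_set")
}

#' @export
print.source_set <- function(x, ...) {
  cat(sprintf("<source_set> %d locations, %d MEG components\n",
              nrow(x$locations), 2L * nrow(x$locations)))
  invisible(x)
}

n_components <- function(sources) 2L * nrow(sources$locations)

# Canonical layout of the 29-region montage: label, polar angle theta from
# +z and azimuth phi from +x (degrees). Midline labels end in M; lateral
# regions come in left/right pairs (suffix L/R), the right-side azimuth
# mirrored across the sagittal plane. This layout is a documented stand-in
# for the published montage coordinates, which are not in the public domain;
# it can be overridden from JSON via read_source_set_json().
br29_layout <- function() {
  mid <- data.frame(
    label = c("FpM", "FCM", "CM", "PM", "OM"),
    theta = c(70, 35, 8, 35, 75),
    phi   = c(90, 90, 90, 270, 270), stringsAsFactors = FALSE)
  right <- data.frame(
    label = c("FR", "FC6R", "FTR", "TAR", "TPR", "CR",
              "CPR", "PR", "POR", "OR", "OTR", "INR"),
    theta = c(45, 55, 75, 90, 95, 35, 45, 50, 65, 80, 95, 85),
    phi   = c(60, 35, 55, 20, 340, 15, 330, 300, 285, 280, 310, 5),
    stringsAsFactors = FALSE)
  left <- right
  left$label <- sub("R$", "L", left$label)
  left$phi <- (180 - right$phi) %% 360
  rbind(mid, right, left)
}

#' Canonical 29-region source layout
#'
#' The 29 labeled regional-source locations of the montage, on a spherical
#' shell at `shell_radius` about the sphere center: 5 midline regions and 12
#' left/right pairs covering frontal, central, temporal, parietal and
#' occipital cortex. Each location carries its tangential basis.
#'
#' @param sphere a [sphere_model()].
#' @param shell_radius shell radius in meters (default 70 mm).
#' @return a `source_set` with 29 locations (58 MEG components).
#' @export
make_br29_locations <- function(sphere = sphere_model(), shell_radius = 0.07) {
  if (shell_radius <= 0) stop("shell_radius must be positive", call. = FALSE)
  lay <- br29_layout()
  th <- lay$theta * pi / 180
  ph <- lay$phi * pi / 180
  pos <- shell_radius * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  pos <- sweep(pos, 2, sphere$center, `+`)
  regional_source_set(lay$label, pos, sphere)
}

#' Subdivided octahedron source grid
#'
#' Recursive 4-way triangle subdivision of a unit octahedron with vertices
#' re-projected onto the unit sphere; the standard construction for source
#' grids. Vertex count is 4^(levels+1) + 2 (level 5: 4098). Normals are the
#' radial directions; adjacency is the 1-ring of the final mesh.
#'
#' @param levels non-negative subdivision depth (practical bound 7).
#' @param radius scale applied to the unit sphere, meters.
#' @param center translation applied after scaling.
#' @param hemisphere label ("left"/"right"/"none").
#' @return object of class `cortical_grid` with `vertices`, `normals`,
#'   `faces`, `adjacency`, `hemisphere`.
#' @export
subdivide_octahedron <- function(levels, radius = 1, center = c(0, 0, 0),
                                 hemisphere = "none") {
  if (levels < 0) stop("levels must be non-negative", call. = FALSE)
  if (levels > 7) stop("levels > 7 not supported", call. = FALSE)
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (lv in seq_len(levels)) {
    edge_mid <- new.env(hash = TRUE, parent = emptyenv())
    verts <- v
    nv <- nrow(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- edge_mid[[key]]
      if (!is.null(m)) return(m)
      nv <<- nv + 1L
      verts <<- rbind(verts, unit(v[i, ] + v[j, ]))
      edge_mid[[key]] <- nv
      nv
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(4 * t - 3):(4 * t), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  adj <- lapply(seq_len(nrow(v)), function(i) integer(0))
  for (t in seq_len(nrow(f))) {
    tri <- f[t, ]
    for (e in list(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])) {
      adj[[e[1]]] <- c(adj[[e[1]]], e[2])
      adj[[e[2]]] <- c(adj[[e[2]]], e[1])
    }
  }
  adj <- lapply(adj, function(a) sort(unique(a)))
  vertices <- sweep(v * radius, 2, center, `+`)
  structure(list(vertices = vertices, normals = v, faces = f,
                 adjacency = adj, hemisphere = hemisphere,
                 radius = radius, center = center, levels = levels),
            class = "cortical_grid")
}

#' Per-hemisphere cortical source grids
#'
#' Two subdivided-octahedron spheres standing in for segmented cortical
#' surfaces: radius 60 mm, centers shifted 6 mm laterally (x). A smooth
#' sphere's normals would be almost purely radial with respect to the head
#' model — and radial dipoles are magnetically silent — whereas cortical
#' surface normals sweep through every obliquity as the surface folds
#' through gyral crowns and sulcal walls. The synthetic folding field
#' emulates this: the dipole normal at each vertex is the radial direction
#' tilted by an angle that cycles with position at a gyral-scale spatial
#' frequency (`fold_frequency` obliquity cycles pole-to-pole; the default
#' gives a fold wavelength of roughly 19 mm on a 60 mm sphere), about a
#' tangential azimuth that likewise rotates with position. The field is a
#' deterministic function of vertex position.
#'
#' @param levels subdivision depth (5 gives 4098 vertices per hemisphere).
#' @param radius grid sphere radius, meters.
#' @param lateral_shift center offset along x, meters.
#' @param fold_frequency obliquity cycles from pole to pole (0 keeps pure
#'   radial normals).
#' @return list with `left` and `right` `cortical_grid`s.
#' @export
make_hemisphere_grids <- function(levels = 5L, radius = 0.06,
                                  lateral_shift = 0.006,
                                  fold_frequency = 10) {
  mk <- function(center, hemi) {
    g <- subdivide_octahedron(levels, radius, center, hemi)
    if (fold_frequency > 0) g$normals <- fold_normals(g, fold_frequency)
    g
  }
  list(left  = mk(c(-lateral_shift, 0, 0), "left"),
       right = mk(c(lateral_shift, 0, 0), "right"))
}

# Synthetic cortical-folding orientation field: tilt each radial normal by
# psi = f * theta about a tangential azimuth chi = f * phi (theta, phi the
# vertex's spherical coordinates on its grid sphere).
fold_normals <- function(grid, fold_frequency) {
  u <- grid$normals
  th <- acos(pmin(1, pmax(-1, u[, 3])))
  ph <- atan2(u[, 2], u[, 1])
  psi <- fold_frequency * th
  chi <- fold_frequency * ph
  out <- matrix(0, nrow(u), 3)
  sph0 <- sphere_model(c(0, 0, 0))
  for (i in seq_len(nrow(u))) {
    tb <- tangential_basis(u[i, ], sph0)
    tdir <- cos(chi[i]) * tb$e_theta + sin(chi[i]) * tb$e_phi
    out[i, ] <- cos(psi[i]) * u[i, ] + sin(psi[i]) * tdir
  }
  out
}

#' Distance from a source position to the nearest sensor
#'
#' @param position numeric length-3 (or a single-row of a source set),
#'   meters.
#' @param array a `sensor_array`.
#' @return minimum Euclidean distance in meters.
#' @export
nearest_sensor_distance <- function(position, array) {
  if (n_channels(array) < 1L) stop("sensor array is empty", call. = FALSE)
  p <- channel_positions(array)
  sqrt(min(rowSums(sweep(p, 2, as.numeric(position))^2)))
}
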