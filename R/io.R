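#' Write / read a sensor array as JSON
#'
#' Schema: an object with `frame`, `meta`, and `channels`, the latter an
#' array of objects with `name`, `kind`, `position_m`, `orientation`,
#' `normal`, `noise_sd`, `baseline_m`.
#'
#' @param array a `sensor_array`.
#' @param path file path.
#' @return `write_*` returns the path invisibly; `read_*` the object.
#' @export
write_sensor_array_json <- function(array, path) {
  ch <- array$channels
  chans <- lapply(seq_len(nrow(ch)), function(i) list(
    name = ch$name[i], kind = ch$kind[i],
    position_m = c(ch$x[i], ch$y[i], ch$z[i]),
    orientation = c(ch$ox[i], ch$oy[i], ch$oz[i]),
    normal = c(ch$nx[i], ch$ny[i], ch$nz[i]),
    noise_sd = ch$noise_sd[i],
    baseline_m = if (is.na(ch$baseline[i])) NULL else ch$baseline[i]))
  jsonlite::write_json(list(frame = array$frame, meta = array$meta,
                            channels = chans),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sensor_array_json
#' @export
read_sensor_array_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(j$channels, function(c0) data.frame(
    name = c0$name, kind = c0$kind,
    x = c0$position_m[[1]], y = c0$position_m[[2]], z = c0$position_m[[3]],
    ox = c0$orientation[[1]], oy = c0$orientation[[2]],
    oz = c0$orientation[[3]],
    nx = c0$normal[[1]], ny = c0$normal[[2]], nz = c0$normal[[3]],
    noise_sd = c0$noise_sd,
    baseline = if (is.null(c0$baseline_m)) NA_real_ else c0$baseline_m,
    stringsAsFactors = FALSE))
  sensor_array(do.call(rbind, rows), frame = j$frame,
               meta = if (is.null(j$meta)) list() else j$meta)
}

#' Write / read a regional source set as JSON
#'
#' Schema: `sphere_center_m` plus `locations`, an array of objects with
#' `label` and `position_m`; tangential bases are reattached on read so a
#' user-supplied coordinate file only needs labels and positions.
#'
#' @param sources a `source_set`.
#' @param path file path.
#' @export
write_source_set_json <- function(sources, path) {
  loc <- sources$locations
  locs <- lapply(seq_len(nrow(loc)), function(i) list(
    label = loc$label[i], position_m = c(loc$x[i], loc$y[i], loc$z[i])))
  jsonlite::write_json(list(sphere_center_m = sources$sphere$center,
                            locations = locs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_source_set_json
#' @export
read_source_set_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  sph <- sphere_model(unlist(j$sphere_center_m))
  labels <- vapply(j$locations, function(l) l$label, "")
  pos <- t(vapply(j$locations, function(l) unlist(l$position_m), numeric(3)))
  regional_source_set(labels, pos, sph)
}

#' Persist / load a montage operator
#'
#' JSON container holding the transform matrix (row-major nested arrays),
#' regularization, channel and component orders, depth weights and the
#' diagonal whitener — everything needed to re-apply the stored inverse to
#' continuous data.
#'
#' @param op a `montage_operator`.
#' @param path file path.
#' @export
write_montage_json <- function(op, path) {
  if (is.matrix(op$whitener))
    stop("only diagonal-whitener operators serialize to JSON", call. = FALSE)
  jsonlite::write_json(list(
    lambda_frac = op$lambda_frac,
    channel_order = op$channel_order,
    component_label = op$component_order$label,
    component_name = op$component_order$component,
    depth_weights = op$depth_weights,
    whitener_diag = op$whitener,
    transform = op$transform,
    gram = op$gram),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_montage_json
#' @export
read_montage_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(transform = j$transform, lambda_frac = j$lambda_frac,
                 whitener = j$whitener_diag, depth_weights = j$depth_weights,
                 gram = j$gram, channel_order = j$channel_order,
                 component_order = data.frame(
                   label = j$component_label,
                   component = j$component_name,
                   stringsAsFactors = FALSE)),
            class = "montage_operator")
}

#' Export a recording or source waveforms as TSV plus JSON sidecar
#'
#' Writes a channels x time matrix as TSV (one row per channel, first
#' column the channel name) with a JSON sidecar (`<path>.json`) carrying
#' sampling rate, units and annotations.
#'
#' @param x a `meg_recording` or `source_waveforms`.
#' @param path TSV file path.
#' @param units unit string recorded in the sidecar.
#' @export
write_timeseries_tsv <- function(x, path, units = NULL) {
  if (inherits(x, "meg_recording")) {
    names_ <- x$channel_names
    meta <- list(fs_hz = x$fs, units = units %||% "T or T/m",
                 annotations = x$annotations)
  } else {
    names_ <- if (!is.null(x$component_order))
      paste(x$component_order$label, x$component_order$component, sep = "/")
    else as.character(seq_len(nrow(x$data)))
    meta <- list(fs_hz = x$fs, units = units %||% "A*m", mode = x$mode)
  }
  utils::write.table(data.frame(channel = names_, x$data,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
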