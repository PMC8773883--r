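#' Measurement noise model
#'
#' Either a diagonal model given by per-channel noise SDs (the default in
#' unaveraged epochs: 200 fT magnetometers, 50 fT/cm gradiometers) or a
#' full symmetric positive-definite covariance.
#'
#' @param sds per-channel noise SD in channel units (diagonal case).
#' @param covariance M x M covariance matrix (full case).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sds = NULL, covariance = NULL) {
  if (!is.null(sds) && !is.null(covariance))
    stop("give either sds or covariance, not both", call. = FALSE)
  if (!is.null(sds)) {
    if (!all(is.finite(sds)) || !all(sds > 0))
      stop("noise SDs must be positive and finite", call. = FALSE)
    return(structure(list(kind = "diagonal", sds = as.numeric(sds)),
                     class = "noise_model"))
  }
  if (is.null(covariance)) stop("empty noise model", call. = FALSE)
  covariance <- as.matrix(covariance)
  if (!isSymmetric(unname(covariance), tol = 1e-8))
    stop("covariance must be symmetric", call. = FALSE)
  structure(list(kind = "full", covariance = covariance),
            class = "noise_model")
}

#' Default diagonal noise model of a sensor array
#'
#' @param array a `sensor_array`; its per-channel `noise_sd` values become
#'   the diagonal model.
#' @return a diagonal `noise_model`.
#' @export
default_noise_model <- function(array) noise_model(sds = array$channels$noise_sd)

#' Noise whitener
#'
#' For the diagonal model returns the vector diag(1/sigma_i) (applied as a
#' row scaling); for a full covariance, the symmetric inverse square root
#' C^(-1/2).
#'
#' @param noise a [noise_model()].
#' @return numeric vector (diagonal case) or symmetric matrix.
#' @export
build_whitener <- function(noise) {
  if (noise$kind == "diagonal") return(1 / noise$sds)
  e <- eigen(noise$covariance, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("noise covariance is not positive definite", call. = FALSE)
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

apply_whitener <- function(W, X) {
  if (is.matrix(W)) W %*% X else X * W
}

#' Build the source-montage operator
#'
#' Constructs the stored linear inverse mapping raw multichannel data to
#' regional-source amplitudes. With whitener W_b and depth weights W_s (the
#' column norms of W_b L), the normalized lead field L_n = W_b L W_s^-1 has
#' a unit-diagonal Gram matrix, the regularized Gram is
#' G = L_n' L_n + lambda I (so lambda is a percentage-scale fraction:
#' 2 percent = 0.02), and the montage transform is
#' W_s^-1 G^-1 L_n' W_b, yielding physical source amplitudes in A*m.
#'
#' @param L a `lead_field`.
#' @param noise a [noise_model()] (defaulting requires passing one built
#'   from the array, see [default_noise_model()]).
#' @param lambda_frac regularization fraction added to the unit-diagonal
#'   Gram (0.02 = 2 percent).
#' @return object of class `montage_operator` with fields `transform`
#'   (P x M), `lambda_frac`, `whitener`, `depth_weights`, `gram`,
#'   `channel_order`, `component_order`.
#' @export
build_montage <- function(L, noise, lambda_frac = 0.02) {
  if (lambda_frac < 0) stop("lambda_frac must be >= 0", call. = FALSE)
  Wb <- build_whitener(noise)
  WL <- apply_whitener(Wb, L$matrix)
  ws <- sqrt(colSums(WL^2))
  if (any(ws == 0)) {
    bad <- which(ws == 0)[1]
    stop(sprintf("degenerate source component %s/%s has zero lead field",
                 L$col_components$label[bad],
                 L$col_components$component[bad]), call. = FALSE)
  }
  Ln <- sweep(WL, 2, ws, `/`)
  P <- ncol(Ln)
  G <- crossprod(Ln) + diag(lambda_frac, P)
  if (lambda_frac == 0) {
    kap <- kappa(G, exact = TRUE)
    if (kap > 1e12)
      warning(sprintf(
        "unregularized Gram matrix is ill-conditioned (condition %.3g)", kap))
  }
  Ginv_Lnt <- solve(G, t(Ln))                     # P x M
  Tm <- apply_whitener(Wb, t(Ginv_Lnt))           # whiten data side
  transform <- t(Tm) / ws                         # de-normalize to A*m
  structure(list(transform = transform, lambda_frac = lambda_frac,
                 whitener = Wb, depth_weights = ws, gram = G,
                 channel_order = L$row_channels,
                 component_order = L$col_components),
            class = "montage_operator")
}

#' @export
print.montage_operator <- function(x, ...) {
  cat(sprintf(
    "<montage_operator> %d components x %d channels, lambda = %g%%\n",
    nrow(x$transform), ncol(x$transform), 100 * x$lambda_frac))
  invisible(x)
}

#' Apply a source montage to a recording
#'
#' A stateless, sample-by-sample linear transform of the raw channel data
#' into the individual tangential component amplitudes (A*m) of every
#' regional source. Channels are aligned by name; a reordered recording
#' gives identical output.
#'
#' @param op a `montage_operator`.
#' @param recording a `meg_recording` (see [meg_recording()]).
#' @return a `source_waveforms` object in `"components"` mode (P rows).
#' @export
apply_montage <- function(op, recording) {
  idx <- match(op$channel_order, recording$channel_names)
  if (anyNA(idx))
    stop("recording is missing montage channels: ",
         paste(utils::head(op$channel_order[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  comps <- op$transform %*% recording$data[idx, , drop = FALSE]
  source_waveforms(comps, fs = recording$fs, mode = "components",
                   component_order = op$component_order)
}

#' Source waveform container
#'
#' @param data component x time matrix, A*m.
#' @param fs sampling rate, Hz.
#' @param mode `"components"` (2 rows per location), `"rms"` or
#'   `"principal"` (1 row per location).
#' @param component_order data frame describing rows (label, component).
#' @return object of class `source_waveforms`.
#' @export
source_waveforms <- function(data, fs, mode = "components",
                             component_order = NULL) {
  data <- as.matrix(data)
  structure(list(data = data, fs = fs, mode = mode,
                 component_order = component_order),
            class = "source_waveforms")
}

#' @export
print.source_waveforms <- function(x, ...) {
  cat(sprintf("<source_waveforms> %d x %d samples at %g Hz, mode '%s'\n",
              nrow(x$data), ncol(x$data), x$fs, x$mode))
  invisible(x)
}

location_labels <- function(component_order) {
  unique(component_order$label)
}

#' Root-mean-square display mode
#'
#' Collapses the two tangential components of each regional source to one
#' trace: per location and sample, sqrt of the mean squared component
#' amplitude.
#'
#' @param waveforms a `source_waveforms` in components mode.
#' @return a `source_waveforms` in `"rms"` mode with one row per location.
#' @export
rms_mode <- function(waveforms) {
  stopifnot(waveforms$mode == "components")
  X <- waveforms$data
  n_loc <- nrow(X) / 2L
  out <- sqrt((X[2 * seq_len(n_loc) - 1, , drop = FALSE]^2 +
               X[2 * seq_len(n_loc), , drop = FALSE]^2) / 2)
  labs <- location_labels(waveforms$component_order)
  source_waveforms(out, waveforms$fs, "rms",
                   data.frame(label = labs, component = "rms",
                              stringsAsFactors = FALSE))
}

# Closed-form eigendecomposition of the symmetric 2x2 window covariance
# [a b; b c]; returns leading unit eigenvector and both eigenvalues.
eigen2x2 <- function(a, b, c) {
  tr <- a + c
  disc <- sqrt((a - c)^2 + 4 * b^2)
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  # tie-break: near-degenerate spectrum -> larger |e_theta| component
  if (l2 > 0 && l1 / l2 < 1 + 1e-9) {
    u <- c(1, 0)
  } else if (abs(b) > .Machine$double.eps * max(abs(a), abs(c), 1)) {
    u <- if (abs(l1 - a) > abs(l1 - c)) c(b, l1 - a) else c(l1 - c, b)
    u <- u / sqrt(sum(u^2))
  } else {
    u <- if (a >= c) c(1, 0) else c(0, 1)
  }
  list(values = c(l1, l2), vector = u)
}

#' Principal-orientation display mode
#'
#' Per regional source, eigendecomposes the 2x2 second-moment matrix of the
#' two tangential component waveforms over an analysis window; the
#' eigenvector of the largest eigenvalue is the best (maximum-variance)
#' dipole orientation for that window, and the output trace is the
#' projection of the component pair onto it. The orientation must be
#' re-estimated per displayed interval. Sign convention: the projected
#' waveform's largest-magnitude sample in the window is positive. An
#' all-zero window is flagged (`orientation_defined = FALSE`) and yields a
#' zero trace.
#'
#' @param waveforms a `source_waveforms` in components mode.
#' @param window integer sample indices of the analysis window (default:
#'   all samples).
#' @return list with `waveforms` (a `"principal"`-mode `source_waveforms`,
#'   one row per location) and `orientation` (data frame: label,
#'   eigenvalues, orientation components in the (e_theta, e_phi) plane,
#'   principal angle in radians, defined flag).
#' @export
principal_mode <- function(waveforms, window = NULL) {
  stopifnot(waveforms$mode == "components")
  X <- waveforms$data
  TT <- ncol(X)
  if (is.null(window)) window <- seq_len(TT)
  if (length(window) < 1L || min(window) < 1L || max(window) > TT)
    stop("analysis window out of range", call. = FALSE)
  n_loc <- nrow(X) / 2L
  labs <- location_labels(waveforms$component_order)
  out <- matrix(0, n_loc, TT)
  ori <- data.frame(label = labs, lambda1 = 0, lambda2 = 0,
                    u_theta = NA_real_, u_phi = NA_real_,
                    angle = NA_real_, orientation_defined = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(n_loc)) {
    s <- X[(2 * j - 1):(2 * j), , drop = FALSE]
    sw <- s[, window, drop = FALSE]
    a <- sum(sw[1, ]^2); b <- sum(sw[1, ] * sw[2, ]); cc <- sum(sw[2, ]^2)
    if (a + cc == 0) next  # undefined orientation, zero trace
    e <- eigen2x2(a, b, cc)
    u <- e$vector
    p <- u[1] * s[1, ] + u[2] * s[2, ]
    pk <- which.max(abs(p[window]))
    if (p[window][pk] < 0) { u <- -u; p <- -p }
    out[j, ] <- p
    ori$lambda1[j] <- e$values[1]; ori$lambda2[j] <- e$values[2]
    ori$u_theta[j] <- u[1]; ori$u_phi[j] <- u[2]
    ori$angle[j] <- atan2(u[2], u[1])
    ori$orientation_defined[j] <- TRUE
  }
  list(waveforms = source_waveforms(out, waveforms$fs, "principal",
         data.frame(label = labs, component = "principal",
                    stringsAsFactors = FALSE)),
       orientation = ori)
}

#' Condition number of the regularized Gram matrix
#'
#' Ratio between the largest and smallest eigenvalue of
#' G = L_n' L_n + lambda I; the stability diagnostic of the montage. Since
#' adding lambda shifts the whole spectrum up, the condition number is
#' strictly decreasing in lambda.
#'
#' @param op a `montage_operator`.
#' @return positive scalar.
#' @export
condition_number <- function(op) {
  ev <- eigen(op$gram, symmetric = TRUE, only.values = TRUE)$values
  max(ev) / min(ev)
}
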