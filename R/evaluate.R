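#' SNR analysis windows
#'
#' Epoch segmentation for the baseline/signal SNR statistic: epochs of
#' `epoch_length` samples starting at t = 0, a baseline window and a
#' disjoint signal window inside each epoch. Defaults match the simulation
#' protocol: 1000-ms epochs at 1000 Hz, samples 1-800 baseline, 801-1000
#' signal, 10 epochs.
#'
#' @param fs sampling rate, Hz.
#' @param epoch_s epoch length, s.
#' @param baseline_s baseline window length at the start of each epoch, s.
#' @return object of class `snr_windows` with integer index vectors
#'   `baseline` and `signal` (within-epoch), `epoch_length`.
#' @export
snr_windows <- function(fs = 1000, epoch_s = 1, baseline_s = 0.8) {
  ne <- round(epoch_s * fs)
  nb <- round(baseline_s * fs)
  if (nb < 1L || nb >= ne)
    stop("baseline must be non-empty and shorter than the epoch",
         call. = FALSE)
  structure(list(baseline = seq_len(nb), signal = (nb + 1L):ne,
                 epoch_length = ne, fs = fs), class = "snr_windows")
}

n_whole_epochs <- function(TT, windows) TT %/% windows$epoch_length

#' Baseline-referenced SNR in dB
#'
#' Per epoch, the mean squared deviation from the epoch's baseline mean is
#' computed over the signal window and over the baseline window;
#' the per-epoch SNR is 20*log10 of their ratio (the convention used as
#' printed throughout, rather than 10*log10 of the power ratio), and the
#' reported value is the arithmetic mean over whole epochs. Partial
#' trailing epochs are dropped. A zero-power baseline yields an `Inf`
#' sentinel for that epoch; epochs with `Inf` are excluded from the average
#' with a warning (all-`Inf` channels report `Inf`).
#'
#' @param x numeric vector (one trace) or channels x time matrix.
#' @param windows an [snr_windows()].
#' @return per-channel epoch-averaged SNR in dB (numeric vector; scalar
#'   for a vector input).
#' @export
snr_db <- function(x, windows) {
  X <- if (is.matrix(x)) x else matrix(x, 1)
  ne <- n_whole_epochs(ncol(X), windows)
  if (ne < 1L) stop("data shorter than one epoch", call. = FALSE)
  db <- matrix(NA_real_, nrow(X), ne)
  for (e in seq_len(ne)) {
    off <- (e - 1L) * windows$epoch_length
    base <- X[, off + windows$baseline, drop = FALSE]
    sig <- X[, off + windows$signal, drop = FALSE]
    ave <- rowMeans(base)
    pb <- rowMeans((base - ave)^2)
    ps <- rowMeans((sig - ave)^2)
    db[, e] <- ifelse(pb > 0, 20 * log10(ps / pb), Inf)
  }
  if (any(is.infinite(db)))
    warning("zero baseline power in some epochs; Inf sentinel excluded ",
            "from epoch averages")
  out <- apply(db, 1, function(v) {
    fin <- v[is.finite(v)]
    if (length(fin)) mean(fin) else Inf
  })
  if (is.matrix(x)) out else out[[1]]
}

#' Best channel by SNR
#'
#' @param snr named (or unnamed) numeric vector of per-channel SNRs.
#' @param labels optional channel labels.
#' @return list with `label`, `index`, `snr`; ties broken by lowest index.
#' @export
best_channel <- function(snr, labels = names(snr)) {
  if (length(snr) < 1L) stop("no channels", call. = FALSE)
  i <- which.max(snr)
  list(label = if (is.null(labels)) as.character(i) else labels[i],
       index = i, snr = snr[[i]])
}

#' Detectability count
#'
#' Number of channels whose SNR reaches the visual-detectability threshold
#' (default 15 dB, inclusive). Zero means the source is not detectable.
#'
#' @param snr numeric vector of per-channel SNRs, dB.
#' @param threshold_db detection threshold, dB.
#' @return integer count.
#' @export
ndt_count <- function(snr, threshold_db = 15) {
  sum(snr >= threshold_db)
}

# Per-location evaluation of montage component waveforms. SNR: per epoch,
# the principal orientation is estimated from the signal window, the
# component pair is projected over the whole epoch, the epoch SNR is taken
# and averaged over epochs. Amplitude: the orientation is estimated from
# the pooled signal-window covariance, the projected waveform is averaged
# time-locked across epochs (bursts repeat once per period), and the peak
# absolute value within the signal window of the averaged epoch is the
# readout — averaging first avoids the upward bias that peak-picking on a
# noisy trace would add. `comps` is P x T (physical A*m).
montage_channel_eval <- function(comps, windows) {
  n_loc <- nrow(comps) / 2L
  ne <- n_whole_epochs(ncol(comps), windows)
  el <- windows$epoch_length
  snr2 <- numeric(n_loc)
  amp <- numeric(n_loc)
  for (j in seq_len(n_loc)) {
    s <- comps[(2 * j - 1):(2 * j), , drop = FALSE]
    dbs <- numeric(ne)
    ca <- 0; cb <- 0; cc2 <- 0   # pooled signal-window second moments
    avg_epoch <- matrix(0, 2, el)
    for (e in seq_len(ne)) {
      off <- (e - 1L) * el
      sw <- s[, off + windows$signal, drop = FALSE]
      a <- sum(sw[1, ]^2); b <- sum(sw[1, ] * sw[2, ]); cc <- sum(sw[2, ]^2)
      ca <- ca + a; cb <- cb + b; cc2 <- cc2 + cc
      avg_epoch <- avg_epoch + s[, off + seq_len(el), drop = FALSE] / ne
      if (a + cc == 0) { dbs[e] <- -Inf; next }
      u <- eigen2x2(a, b, cc)$vector
      ep <- s[, off + seq_len(el), drop = FALSE]
      p <- u[1] * ep[1, ] + u[2] * ep[2, ]
      ave <- mean(p[windows$baseline])
      pb <- mean((p[windows$baseline] - ave)^2)
      ps <- mean((p[windows$signal] - ave)^2)
      dbs[e] <- if (pb > 0) 20 * log10(ps / pb) else Inf
    }
    fin <- dbs[is.finite(dbs)]
    snr2[j] <- if (length(fin)) mean(fin) else Inf
    if (ca + cc2 > 0) {
      u <- eigen2x2(ca, cb, cc2)$vector
      pavg <- u[1] * avg_epoch[1, ] + u[2] * avg_epoch[2, ]
      amp[j] <- max(abs(pavg[windows$signal]))
    }
  }
  list(snr2 = snr2, amp = amp)
}

#' Amplitude readout at the best montage channel
#'
#' Peak absolute value, within the signal window, of the epoch-averaged
#' principal-orientation waveform of the best-SNR regional source
#' (orientation from the pooled signal-window covariance; epochs averaged
#' time-locked before peak-picking so the readout is not inflated by
#' background noise).
#'
#' @param waveforms a components-mode `source_waveforms` (physical A*m).
#' @param windows an [snr_windows()].
#' @return list with `label`, `amp` (A*m), `snr2` (dB), and the per-location
#'   vectors `snr2_all`, `amp_all`.
#' @export
amplitude_readout <- function(waveforms, windows) {
  stopifnot(waveforms$mode == "components")
  ev <- montage_channel_eval(waveforms$data, windows)
  labs <- location_labels(waveforms$component_order)
  i <- best_source_index(ev)
  list(label = labs[i], amp = ev$amp[i], snr2 = ev$snr2[i],
       snr2_all = ev$snr2, amp_all = ev$amp)
}

# Best montage channel: maximum SNR, ties (notably the +Inf sentinel of
# noiseless baselines) resolved by the larger amplitude, then lowest index.
best_source_index <- function(ev) {
  cand <- which(ev$snr2 == max(ev$snr2))
  cand[which.max(ev$amp[cand])]
}

# Euclidean distance between two 3-vectors.
dist3 <- function(a, b) sqrt(sum((a - b)^2))

#' Detectability study over a set of simulated sources
#'
#' The end-to-end evaluation loop of the simulation study: for every source
#' definition in the scenario, simulate its recording over the shared
#' background, band-pass, apply montages built at each regularization, and
#' report sensor-level and source-level SNR, detectability counts,
#' amplitudes and distances.
#'
#' Because the band-pass is linear and time-invariant and a fixed source's
#' sensor signal is (spatial pattern) x (time course), the background and
#' the burst waveform are filtered once and recombined per source — exactly
#' equal to filtering each simulated recording in full.
#'
#' @param scn a `meg_scenario` from [run_scenario()].
#' @param lambdas numeric vector of regularization fractions.
#' @param subset channel subset passed to [subset_channels()].
#' @param windows an [snr_windows()]; defaults to the scenario's sampling
#'   rate.
#' @param threshold_db detectability threshold, dB.
#' @param noise optional `noise_model` for montage building; defaults to
#'   the subset's nominal diagonal model.
#' @param band band-pass edges, Hz.
#' @return object of class `snr_report`: data frame with one row per
#'   source x lambda (label, lambda, snr1, ndt1, snr2, ndt2, amp_nAm,
#'   d1_mm, d2_mm, best_sensor, best_source), with the montage operators in
#'   `attr(, "operators")`.
#' @export
run_detectability_study <- function(scn, lambdas = c(0, 0.01, 0.02),
                                    subset = "all", windows = NULL,
                                    threshold_db = 15, noise = NULL,
                                    band = c(2, 70)) {
  arr <- subset_channels(scn$array, subset)
  fs <- scn$spec$fs
  if (is.null(windows)) windows <- snr_windows(fs = fs)
  if (is.null(noise)) noise <- default_noise_model(arr)

  L <- build_leadfield(scn$source_set, arr, scn$sphere)
  bg <- synth_background(arr, fs, scn$spec$duration, scn$spec$seed)
  noise_f <- bandpass_filter(bg$data, fs, band)
  wave_f <- bandpass_filter(make_burst_waveform(scn$spec$burst, fs,
                                                scn$spec$duration), fs, band)
  ops <- lapply(lambdas, function(l) build_montage(L, noise, l))
  src_noise <- lapply(ops, function(op) op$transform %*% noise_f)

  loc <- scn$source_set$locations
  loc_pos <- as.matrix(loc[, c("x", "y", "z")])
  labs <- loc$label
  rows <- vector("list", length(scn$sources) * length(lambdas))
  ri <- 0L
  for (i in seq_along(scn$sources)) {
    src <- scn$sources[[i]]
    pattern <- dipole_pattern(arr, src$positions, src$moments, scn$sphere)
    sens <- pattern %o% wave_f + noise_f
    snr1 <- snr_db(sens, windows)
    b1 <- best_channel(snr1, arr$channels$name)
    nd1 <- ndt_count(snr1, threshold_db)
    ctr <- colMeans(matrix(src$positions, ncol = 3))
    d1 <- nearest_sensor_distance(ctr, arr)
    for (k in seq_along(lambdas)) {
      w <- ops[[k]]$transform %*% pattern
      comps <- w %*% matrix(wave_f, 1) + src_noise[[k]]
      ev <- montage_channel_eval(comps, windows)
      bi <- best_source_index(ev)
      b2 <- list(label = labs[bi], index = bi, snr = ev$snr2[bi])
      d2 <- dist3(ctr, loc_pos[b2$index, ])
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        label = src$label, lambda = lambdas[k],
        snr1 = b1$snr, ndt1 = nd1,
        snr2 = b2$snr, ndt2 = ndt_count(ev$snr2, threshold_db),
        amp_nAm = ev$amp[b2$index] * 1e9,
        d1_mm = d1 * 1000, d2_mm = d2 * 1000,
        best_sensor = b1$label, best_source = b2$label,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "operators") <- ops
  attr(out, "windows") <- windows
  attr(out, "threshold_db") <- threshold_db
  class(out) <- c("snr_report", class(out))
  out
}

#' Regularization sweep over channel subsets
#'
#' Runs the montage-location scenario for each channel subset (all
#' channels, gradiometers only, magnetometers only) and regularization
#' value, reporting the mean best-channel source-level SNR and mean
#' best-channel amplitude over the scenario sources, plus the mean
#' sensor-level SNR per subset.
#'
#' @param scn a `meg_scenario`.
#' @param lambdas regularization fractions (default the sweep grid
#'   0, 0.5, 1, 2, 3, 4, 5 percent).
#' @param subsets named list of channel-subset selectors.
#' @param ... passed to [run_detectability_study()].
#' @return data frame: subset, lambda, mean_snr1, mean_snr2, mean_amp_nAm.
#' @export
regularization_sweep <- function(scn,
                                 lambdas = c(0, .005, .01, .02, .03, .04, .05),
                                 subsets = list(
                                   all = "all",
                                   gradiometers = "planar_gradiometer",
                                   magnetometers = "magnetometer"),
                                 ...) {
  rows <- list()
  for (sn in names(subsets)) {
    rep <- run_detectability_study(scn, lambdas = lambdas,
                                   subset = subsets[[sn]], ...)
    for (l in lambdas) {
      r <- rep[rep$lambda == l, ]
      rows[[length(rows) + 1L]] <- data.frame(
        subset = sn, lambda = l,
        mean_snr1 = mean(r$snr1), mean_snr2 = mean(r$snr2),
        mean_amp_nAm = mean(r$amp_nAm), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summary statistics of a detectability study
#'
#' Mean, median and maximum of the best sensor SNR, best source SNR,
#' detectability counts and best-channel amplitude, per regularization
#' value (sources with Ndt = 0 included in the means), plus the number of
#' sources detectable on at least one channel.
#'
#' @param report an `snr_report` from [run_detectability_study()].
#' @param by optional column name to additionally group by (e.g. a
#'   hemisphere column added by the caller).
#' @return data frame of summary rows.
#' @export
summarize_scenario <- function(report, by = NULL) {
  groups <- if (is.null(by)) list(all = report)
            else split(report, report[[by]])
  rows <- list()
  for (g in names(groups)) {
    rep <- groups[[g]]
    for (l in sort(unique(rep$lambda))) {
      r <- rep[rep$lambda == l, ]
      for (stat in c("mean", "median", "max")) {
        f <- get(stat)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, lambda = l, stat = stat,
          snr1 = f(r$snr1), ndt1 = f(r$ndt1),
          snr2 = f(r$snr2), ndt2 = f(r$ndt2),
          amp_nAm = f(r$amp_nAm),
          n_detect_sensor = sum(r$ndt1 > 0),
          n_detect_source = sum(r$ndt2 > 0),
          n_sources = nrow(r), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-vertex SNR map table
#'
#' Joins per-vertex detectability results to the grid geometry in a plain
#' table a surface renderer can consume.
#'
#' @param grid a `cortical_grid`.
#' @param values data frame with one row per grid vertex (e.g. a subset of
#'   an `snr_report` for one lambda, in vertex order) holding at least
#'   `snr1` and `snr2`.
#' @return data frame: vertex, x, y, z, nx, ny, nz, then the value columns.
#' @export
snr_map_export <- function(grid, values) {
  nv <- nrow(grid$vertices)
  if (nrow(values) != nv)
    stop("need exactly one value row per grid vertex", call. = FALSE)
  cbind(data.frame(vertex = seq_len(nv),
                   x = grid$vertices[, 1], y = grid$vertices[, 2],
                   z = grid$vertices[, 3],
                   nx = grid$normals[, 1], ny = grid$normals[, 2],
                   nz = grid$normals[, 3]),
        values)
}
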