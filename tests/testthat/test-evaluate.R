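sph <- sphere_model()

test_that("SNR statistic matches the brute-force summation oracle", {
  win <- snr_windows()
  set.seed(31)
  for (i in 1:10) {
    x <- stats::rnorm(10000, mean = stats::runif(1, -2, 2))
    expect_equal(snr_db(x, win), oracle_snr_db(x, win), tolerance = 1e-10)
  }
  # matrix input evaluates each row independently
  X <- matrix(stats::rnorm(3 * 5000), 3)
  got <- snr_db(X, win)
  expect_equal(got, apply(X, 1, oracle_snr_db, windows = win),
               tolerance = 1e-10)
})

test_that("SNR has the printed 20*log10 convention and scale invariance", {
  win <- snr_windows()
  # baseline +-1 alternating (power 1, mean 0), signal +-sqrt(10):
  # power ratio 10 => 20 dB under the printed convention
  ep <- c(rep(c(1, -1), 400), rep(c(sqrt(10), -sqrt(10)), 100))
  x <- rep(ep, 10)
  expect_equal(snr_db(x, win), 20, tolerance = 1e-12)
  # identical statistics in the two windows: 0 dB
  ep0 <- c(rep(c(1, -1), 400), rep(c(1, -1), 100))
  expect_equal(snr_db(rep(ep0, 10), win), 0, tolerance = 1e-12)
  # scaling a trace leaves its SNR unchanged
  set.seed(32)
  y <- stats::rnorm(10000)
  expect_equal(snr_db(y * 3.7e-13, win), snr_db(y, win), tolerance = 1e-9)
  # zero baseline power -> Inf sentinel with a warning
  z <- rep(c(rep(0, 800), rep(c(1, -1), 100)), 2)
  expect_warning(v <- snr_db(z, win), "Inf")
  expect_identical(v, Inf)
})

test_that("best channel and detectability counts match exhaustive scans", {
  expect_equal(best_channel(c(a = 3, b = 9, c = 9))$label, "b")
  expect_equal(best_channel(c(solo = 4))$label, "solo")
  set.seed(33)
  for (i in 1:20) {
    v <- stats::rnorm(50, 10, 8)
    expect_equal(best_channel(v)$index, which(v == max(v))[1])
    expect_equal(ndt_count(v, 15), sum(vapply(v, function(s) s >= 15, NA)))
  }
  expect_equal(ndt_count(c(14.9, 2, -3)), 0L)
  expect_equal(ndt_count(c(15, 15.1, 2)), 2L)   # threshold is inclusive
})

test_that("noiseless montage-location source reads out 100 nAm at lambda 0", {
  arr <- make_synthetic_helmet(40)
  src <- make_br29_locations(sph)
  L <- build_leadfield(src, arr)
  op0 <- build_montage(L, default_noise_model(arr), 0)
  loc <- src$locations[10, ]
  mom <- (c(loc$e1x, loc$e1y, loc$e1z) + c(loc$e2x, loc$e2y, loc$e2z)) /
    sqrt(2)
  wave <- make_burst_waveform(burst_spec(), 1000, 2)
  pattern <- dipole_pattern(arr, matrix(c(loc$x, loc$y, loc$z), 1),
                            matrix(mom, 1), sph)
  comps <- op0$transform %*% (pattern %o% wave)
  wf <- source_waveforms(comps, 1000, "components", op0$component_order)
  ev <- amplitude_readout(wf, snr_windows())
  expect_equal(ev$label, loc$label)
  expect_equal(ev$amp * 1e9, 100, tolerance = 5e-3)
  # stronger regularization reads out less
  op2 <- build_montage(L, default_noise_model(arr), 0.02)
  comps2 <- op2$transform %*% (pattern %o% wave)
  ev2 <- amplitude_readout(source_waveforms(comps2, 1000, "components",
                                            op2$component_order),
                           snr_windows())
  expect_lt(ev2$amp, ev$amp)
})

test_that("orientation recovery is within 5 degrees at high SNR", {
  arr <- make_synthetic_helmet(40)
  src <- make_br29_locations(sph)
  L <- build_leadfield(src, arr)
  # lambda = 0: regularization would itself bias orientations via
  # cross-talk, the recovery property concerns the unbiased inverse
  op <- build_montage(L, default_noise_model(arr), 0)
  set.seed(34)
  win <- snr_windows()
  for (j in c(3, 11, 20)) {
    loc <- src$locations[j, ]
    ang <- stats::runif(1, 0, 2 * pi)
    mom <- cos(ang) * c(loc$e1x, loc$e1y, loc$e1z) +
           sin(ang) * c(loc$e2x, loc$e2y, loc$e2z)
    bg <- synth_background(arr, 1000, 2, seed = 40 + j)
    # strong source (300 nAm) to sit clearly above 30 dB
    rec <- simulate_recording(matrix(c(loc$x, loc$y, loc$z), 1),
                              matrix(mom, 1),
                              burst_spec(amplitude = 3e-7), arr, sph, bg)
    wf <- apply_montage(op, rec)
    pm <- principal_mode(wf, window = 801:1000)
    snr <- snr_db(wf$data[(2 * j - 1):(2 * j), ], win)
    expect_gt(max(snr), 30)   # the fixture is constructed to sit above 30 dB
    u <- c(pm$orientation$u_theta[j], pm$orientation$u_phi[j])
    truth <- c(cos(ang), sin(ang))
    dev <- acos(pmin(1, abs(sum(u * truth)))) * 180 / pi
    expect_lt(dev, 5)
  }
})

test_that("scenario summaries aggregate like hand-computed statistics", {
  rep1 <- data.frame(label = "a", lambda = 0.02, snr1 = 31, ndt1 = 4,
                     snr2 = 25, ndt2 = 2, amp_nAm = 80, d1_mm = 40,
                     d2_mm = 20, best_sensor = "m1", best_source = "s1")
  s1 <- summarize_scenario(rep1)
  expect_equal(s1$snr1, rep(31, 3))
  expect_equal(s1$amp_nAm, rep(80, 3))
  rep3 <- rbind(rep1,
                transform(rep1, label = "b", snr2 = 10, ndt2 = 0,
                          amp_nAm = 50),
                transform(rep1, label = "c", snr2 = 40, ndt2 = 6,
                          amp_nAm = 110))
  s3 <- summarize_scenario(rep3)
  expect_equal(s3$snr2[s3$stat == "mean"], 25)
  expect_equal(s3$snr2[s3$stat == "median"], 25)
  expect_equal(s3$snr2[s3$stat == "max"], 40)
  # sources with ndt2 = 0 stay in the mean and in the counts
  expect_equal(s3$ndt2[s3$stat == "mean"], mean(c(2, 0, 6)))
  expect_equal(unique(s3$n_detect_source), 2L)
})

test_that("SNR map export joins values to grid vertices", {
  g <- subdivide_octahedron(1, radius = 0.06)
  vals <- data.frame(snr1 = rep(20, 18), snr2 = rep(10, 18))
  m <- snr_map_export(g, vals)
  expect_equal(nrow(m), 18L)
  expect_equal(unique(m$snr2), 10)
  expect_true(all(c("vertex", "x", "nz", "snr1") %in% names(m)))
  expect_error(snr_map_export(g, vals[-1, ]), "one value")
})

test_that("study fast path equals the direct simulate-filter-apply pipeline", {
  arr <- make_synthetic_helmet(40)
  src <- make_br29_locations(sph)
  spec <- scenario_spec("montage_locations", duration = 4, seed = 6)
  scn <- run_scenario(spec, arr, src, sph)
  scn$sources <- scn$sources[c(2, 17)]
  win <- snr_windows()
  rep <- run_detectability_study(scn, lambdas = 0.02, windows = win)
  L <- build_leadfield(src, arr)
  op <- build_montage(L, default_noise_model(arr), 0.02)
  for (i in 1:2) {
    rec <- scenario_recording(scn, i)
    snr1 <- snr_db(rec$data, win)
    wf <- apply_montage(op, rec)
    ev <- amplitude_readout(wf, win)
    expect_equal(rep$snr1[i], max(snr1), tolerance = 1e-8)
    expect_equal(rep$ndt1[i], ndt_count(snr1))
    expect_equal(rep$snr2[i], ev$snr2, tolerance = 1e-8)
    expect_equal(rep$amp_nAm[i], ev$amp * 1e9, tolerance = 1e-8)
    expect_equal(rep$best_source[i], ev$label)
  }
})
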