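sph <- sphere_model()

test_that("whitener: diagonal, identity and full-covariance cases", {
  nm <- noise_model(sds = c(2e-13, 5e-12))
  expect_equal(build_whitener(nm), c(1 / 2e-13, 1 / 5e-12))
  expect_equal(build_whitener(noise_model(covariance = diag(3))), diag(3),
               tolerance = 1e-12)
  set.seed(21)
  A <- matrix(stats::rnorm(25), 5)
  C <- crossprod(A) + diag(5) * 0.1
  W <- build_whitener(noise_model(covariance = C))
  expect_equal(W %*% C %*% t(W), diag(5), tolerance = 1e-10)
  expect_error(build_whitener(noise_model(covariance = -diag(3))),
               "positive definite")
  expect_error(noise_model(sds = c(1, -1)), "positive")
})

test_that("montage Gram has a unit diagonal for any noise model and geometry", {
  set.seed(22)
  for (i in 1:5) {
    arr <- tiny_helmet(sample(10:30, 1))
    src <- tiny_sources()
    L <- build_leadfield(src, arr)
    sds <- stats::runif(nrow(arr$channels), 1e-13, 1e-11)
    op <- build_montage(L, noise_model(sds = sds),
                        lambda_frac = stats::runif(1, 0, 0.05))
    expect_lt(max(abs(diag(op$gram) - (1 + op$lambda_frac))), 1e-12)
    expect_true(all(op$depth_weights > 0))
  }
})

test_that("zero regularization inverts a full-rank lead field exactly", {
  arr <- tiny_helmet(20)
  src <- tiny_sources()
  L <- build_leadfield(src, arr)
  op <- build_montage(L, default_noise_model(arr), 0)
  set.seed(23)
  for (i in 1:10) {
    s <- stats::rnorm(12) * 1e-8
    rec <- meg_recording(L$matrix %*% s, fs = 1000, arr$channels$name)
    shat <- apply_montage(op, rec)$data[, 1]
    expect_lt(max(abs(shat - s)) / max(abs(s)), 1e-10)
  }
})

test_that("reconstructed amplitude shrinks monotonically with regularization", {
  arr <- tiny_helmet(20)
  src <- tiny_sources()
  L <- build_leadfield(src, arr)
  s <- rep(1e-8, 12)
  b <- L$matrix %*% s
  rec <- meg_recording(b, 1000, arr$channels$name)
  norms <- vapply(c(0, 0.005, 0.01, 0.02, 0.03, 0.04, 0.05), function(l) {
    op <- build_montage(L, default_noise_model(arr), l)
    sqrt(sum(apply_montage(op, rec)$data[, 1]^2))
  }, 0)
  expect_true(all(diff(norms) < 0))
  # Tikhonov limit: huge lambda kills the output
  oph <- build_montage(L, default_noise_model(arr), 1e8)
  expect_lt(sqrt(sum(apply_montage(oph, rec)$data[, 1]^2)), 1e-6 * norms[1])
})

test_that("apply_montage is linear, stateless and name-aligned", {
  arr <- tiny_helmet(20)
  L <- build_leadfield(tiny_sources(), arr)
  op <- build_montage(L, default_noise_model(arr), 0.02)
  M <- nrow(arr$channels)
  set.seed(24)
  X <- matrix(stats::rnorm(M * 50), M) * 1e-12
  Y <- matrix(stats::rnorm(M * 50), M) * 1e-12
  rec <- function(D, nm = arr$channels$name) meg_recording(D, 1000, nm)
  expect_equal(apply_montage(op, rec(X * 0))$data, matrix(0, 12, 50))
  lhs <- apply_montage(op, rec(2 * X - 3 * Y))$data
  rhs <- 2 * apply_montage(op, rec(X))$data - 3 * apply_montage(op, rec(Y))$data
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # permuted channels give the identical result after name alignment
  perm <- sample(M)
  out1 <- apply_montage(op, rec(X))
  out2 <- apply_montage(op, rec(X[perm, ], arr$channels$name[perm]))
  expect_equal(out2$data, out1$data)
  expect_error(apply_montage(op, rec(X[-1, , drop = FALSE],
                                     arr$channels$name[-1])), "missing")
})

test_that("rms mode averages component power per location", {
  co <- data.frame(label = rep(c("A", "B"), each = 2),
                   component = rep(c("e_theta", "e_phi"), 2))
  wf <- source_waveforms(matrix(c(3, 4, 5, 0), 4, 1), 1000, "components", co)
  r <- rms_mode(wf)
  expect_equal(nrow(r$data), 2L)
  expect_equal(r$data[1, 1], sqrt((9 + 16) / 2))
  expect_equal(r$data[2, 1], 5 / sqrt(2))   # single active component
  expect_equal(r$mode, "rms")
})

test_that("principal mode matches an SVD oracle and flags zero windows", {
  set.seed(25)
  co <- data.frame(label = rep("A", 2), component = c("e_theta", "e_phi"))
  X <- matrix(stats::rnorm(2 * 300), 2)
  wf <- source_waveforms(X, 1000, "components", co)
  pm <- principal_mode(wf)
  sv <- svd(t(X))
  expect_equal(c(pm$orientation$lambda1[1], pm$orientation$lambda2[1]),
               sv$d^2, tolerance = 1e-10)
  u <- c(pm$orientation$u_theta[1], pm$orientation$u_phi[1])
  v1 <- sv$v[, 1]
  expect_equal(abs(sum(u * v1)), 1, tolerance = 1e-10)
  # projection equals the components' projection on the leading axis
  expect_equal(abs(pm$waveforms$data[1, ]), abs(as.numeric(u %*% X)),
               tolerance = 1e-12)

  # fixed-orientation noiseless source: leading axis captures all variance
  mix <- c(0.6, 0.8)
  Xf <- mix %o% sin(seq(0, 10, length.out = 200))
  pf <- principal_mode(source_waveforms(Xf, 1000, "components", co))
  expect_lt(pf$orientation$lambda2[1], 1e-10 * pf$orientation$lambda1[1])
  expect_equal(abs(c(pf$orientation$u_theta[1], pf$orientation$u_phi[1])),
               mix, tolerance = 1e-10)
  # sign convention: the window peak is positive
  expect_gt(max(pf$waveforms$data[1, ]), 0)
  expect_equal(max(abs(pf$waveforms$data[1, ])),
               max(pf$waveforms$data[1, ]))

  # all-zero window: flagged, zero trace
  p0 <- principal_mode(source_waveforms(Xf * 0, 1000, "components", co))
  expect_false(p0$orientation$orientation_defined[1])
  expect_equal(p0$waveforms$data, matrix(0, 1, ncol(Xf)))

  # equal-power orthogonal components: documented tie-break (e_theta axis)
  Xd <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  pd <- principal_mode(source_waveforms(Xd, 1000, "components", co))
  expect_equal(abs(pd$orientation$u_theta[1]), 1)
})

test_that("condition number tracks the Gram spectrum and shrinks with lambda", {
  fake <- structure(list(gram = diag(c(4, 1))), class = "montage_operator")
  expect_equal(condition_number(fake), 4)
  expect_equal(condition_number(structure(list(gram = diag(3)),
                                          class = "montage_operator")), 1)
  arr <- tiny_helmet(20)
  L <- build_leadfield(tiny_sources(), arr)
  nm <- default_noise_model(arr)
  kaps <- vapply(c(0, 0.005, 0.01, 0.02, 0.05),
                 function(l) condition_number(build_montage(L, nm, l)), 0)
  expect_true(all(diff(kaps) < 0))
})

test_that("degenerate (zero lead field) source components are named", {
  arr <- tiny_helmet(10)
  L <- build_leadfield(tiny_sources(), arr)
  L$matrix[, 3] <- 0
  expect_error(build_montage(L, default_noise_model(arr), 0.02),
               "S2/e_theta")
})
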