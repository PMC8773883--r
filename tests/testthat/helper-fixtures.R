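# Shared fixtures and independent oracles, built in code at test time.

tiny_helmet <- function(n_sites = 24L) {
  make_synthetic_helmet(n_sites = n_sites, seed = 1L)
}

# A small regional source set: 6 locations on a 65 mm shell.
tiny_sources <- function(sphere = sphere_model()) {
  th <- c(30, 60, 60, 90, 60, 40) * pi / 180
  ph <- c(90, 30, 150, 270, 260, 200) * pi / 180
  pos <- 0.065 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  regional_source_set(sprintf("S%d", 1:6), pos, sphere)
}

# Independent field oracle: outside a spherical conductor the dipole field
# is B = mu0 * grad(U) with the closed-form scalar potential
# U(r) = (1/4pi) (Q x r0 . r) / F,  F = a (r a + r^2 - r0.r).
# The gradient is taken numerically (central differences), so this never
# touches the implementation's analytic gradient.
oracle_dipole_field <- function(point, q_pos, q_mom, center = c(0, 0, 0),
                                h = 1e-6) {
  U <- function(r) {
    rr <- r - center
    r0 <- q_pos - center
    av <- rr - r0
    a <- sqrt(sum(av^2)); rn <- sqrt(sum(rr^2))
    Fg <- a * (rn * a + rn^2 - sum(r0 * rr))
    qxr0 <- c(q_mom[2] * r0[3] - q_mom[3] * r0[2],
              q_mom[3] * r0[1] - q_mom[1] * r0[3],
              q_mom[1] * r0[2] - q_mom[2] * r0[1])
    sum(qxr0 * rr) / (4 * pi * Fg)
  }
  g <- vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- h
    (U(point + e) - U(point - e)) / (2 * h)
  }, 0)
  4 * pi * 1e-7 * g
}

# Brute-force Eq.-style SNR oracle: explicit loops and running sums.
oracle_snr_db <- function(x, windows) {
  ne <- length(x) %/% windows$epoch_length
  vals <- numeric(ne)
  for (e in seq_len(ne)) {
    off <- (e - 1) * windows$epoch_length
    ave <- 0
    for (i in windows$baseline) ave <- ave + x[off + i]
    ave <- ave / length(windows$baseline)
    pb <- 0
    for (i in windows$baseline) pb <- pb + (x[off + i] - ave)^2
    pb <- pb / length(windows$baseline)
    ps <- 0
    for (i in windows$signal) ps <- ps + (x[off + i] - ave)^2
    ps <- ps / length(windows$signal)
    vals[e] <- 20 * log10(ps / pb)
  }
  mean(vals)
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}
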