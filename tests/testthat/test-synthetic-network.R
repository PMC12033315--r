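test_that("a spec without edges yields a block-diagonal AR(2) model", {
  spec <- network_spec(c("A", "B"),
                       data.frame(f0_hz = c(20, 60), damping = c(0.9, 0.8),
                                  sigma0 = c(1, 2)))
  m <- build_mvar_from_spec(spec, 0)
  expect_equal(m$p, 2L)
  expect_equal(m$A[1, 2, ], c(0, 0))
  expect_equal(m$A[2, 1, ], c(0, 0))
  th <- 2 * pi * 20 / 500
  expect_equal(m$A[1, 1, 1], 2 * 0.9 * cos(th))
  expect_equal(m$A[1, 1, 2], -0.81)
  expect_equal(diag(m$Sigma), c(1, 4))
})

test_that("AR(2) resonator spectrum peaks at its design frequency", {
  spec <- network_spec("A", data.frame(f0_hz = 25, damping = 0.97, sigma0 = 1),
                       fs_hz = 500)
  m <- build_mvar_from_spec(spec, 0)
  f <- seq(1, 100, 0.1)
  ps <- mvar_spectrum(m, f)
  expect_lt(abs(f[which.max(ps[1, ])] - 25), 1)
})

test_that("strengthening an edge strictly increases gPDC at its band centre", {
  mk <- function(g) {
    spec <- network_spec(
      c("STN", "M1"),
      data.frame(f0_hz = c(25, 25), damping = c(0.85, 0.85), sigma0 = c(1, 1)),
      data.frame(src = "STN", dst = "M1", f0_hz = 25, gain = g,
                 level_slope = 0, stop_lo = 55, stop_hi = 110))
    gpdc(build_mvar_from_spec(spec, 0), freqs = 25)
  }
  expect_gt(mk(0.08)$pi_abs[2, 1, 1], mk(0.04)$pi_abs[2, 1, 1])
})

test_that("an unstable construction is refused with the offending edge named", {
  spec <- default_network_spec()
  spec$edges$gain[1] <- 5
  expect_error(build_mvar_from_spec(spec, 0), "STN->M1")
})

test_that("simulated AR(1) variance matches the closed form", {
  m <- mvar_model(array(0.5, c(1, 1, 1)), matrix(1), 500)
  rec <- simulate_mvar(m, 1e5, seed = 3)
  expect_equal(var(rec$data[1, ]), 1 / (1 - 0.25), tolerance = 0.03)
})

test_that("simulation honours zero innovations, seeds, and stability guard", {
  m <- mvar_model(array(0.5, c(1, 1, 1)), matrix(0), 500)
  rec <- simulate_mvar(m, 100, seed = 1)
  expect_equal(max(abs(rec$data)), 0)
  m2 <- random_stable_mvar(3, 2, seed = 8)
  expect_identical(simulate_mvar(m2, 500, seed = 4)$data,
                   simulate_mvar(m2, 500, seed = 4)$data)
  unstable <- mvar_model(array(1.1, c(1, 1, 1)), matrix(1), 500)
  expect_error(simulate_mvar(unstable, 100), "unstable")
})

test_that("band kernels are selective for their own band", {
  fs <- 500
  kb <- design_band_kernel(25, fs, 16, 55, 110)
  resp <- function(k, f) abs(sum(k * exp(-2i * pi * f * seq_along(k) / fs)))
  expect_equal(resp(kb, 25), 1, tolerance = 1e-6)
  expect_lt(max(vapply(seq(61, 100, 0.5), function(f) resp(kb, f),
                       numeric(1))), 0.01)
})

test_that("identity-padded lead field copies sources into the first sensors", {
  src <- simulate_mvar(random_stable_mvar(3, 2, seed = 2), 1000, seed = 5)
  L <- rbind(diag(3), matrix(0, 5, 3))
  lf <- structure(list(matrix = L, source_labels = src$labels,
                       sensor_labels = sprintf("E%02d", 1:8)),
                  class = "lead_field")
  out <- project_to_sensors(src, sensor_model_spec(n_sensors = 8,
                                                   sensor_noise_sd = 0),
                            leadfield = lf)
  expect_equal(out$recording$data[1:3, ], src$data)
  expect_equal(max(abs(out$recording$data[4:8, ])), 0)
})

test_that("stimulation pulse train appears as a sensor-space spectral peak", {
  src <- simulate_mvar(random_stable_mvar(2, 2, seed = 3), 5000, seed = 6)
  ss <- sensor_model_spec(n_sensors = 4, sensor_noise_sd = 0.01,
                          dbs_amp = 2, dbs_rate_hz = 130)
  out <- project_to_sensors(src, ss, seed = 7)
  peak_at <- function(x, fs) {
    ps <- welch_psd(x, fs, win_s = 2)
    at <- mean(ps$psd[abs(ps$freq - 130) <= 0.5])
    flank <- mean(ps$psd[(ps$freq >= 123 & ps$freq <= 127) |
                           (ps$freq >= 133 & ps$freq <= 137)])
    at / flank
  }
  expect_gt(peak_at(out$recording$data[1, ], 500), 10)
  expect_lt(peak_at(src$data[1, ], 500), 3)
})

test_that("lead fields are full rank, unit-norm and reproducible", {
  lf <- make_leadfield(16, 5, seed = 11)
  expect_equal(qr(lf$matrix)$rank, 5)
  expect_equal(colSums(lf$matrix^2), rep(1, 5))
  expect_identical(lf$matrix, make_leadfield(16, 5, seed = 11)$matrix)
  expect_error(make_leadfield(3, 5), "at least as many sensors")
})
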