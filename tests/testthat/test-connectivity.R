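test_that("MVAR least squares recovers a known model", {
  m <- random_stable_mvar(5, 3, seed = 21)
  rec <- simulate_mvar(m, 20000, seed = 1)
  fit <- fit_mvar(rec, order = 3)
  expect_lt(max(abs(fit$A - m$A)), 0.05)
  expect_lt(max(abs(fit$Sigma - diag(5))), 0.1)
  expect_true(attr(fit, "stable_fit"))
})

test_that("the fit agrees with the multivariate Yule-Walker solution", {
  m <- random_stable_mvar(3, 1, seed = 22)
  rec <- simulate_mvar(m, 30000, seed = 2)
  fit <- fit_mvar(rec, order = 1)
  yw <- stats::ar.yw(t(rec$data), aic = FALSE, order.max = 1,
                     demean = TRUE)
  expect_equal(fit$A[, , 1], unname(yw$ar[1, , ]), tolerance = 0.01)
})

test_that("independent channels produce only noise-level cross-coefficients", {
  set.seed(23)
  rec <- mc_recording(matrix(rnorm(4 * 20000), 4), 500)
  fit <- fit_mvar(rec, order = 2)
  off <- fit$A[rep(!diag(4), 2)]
  # OLS standard error of a VAR coefficient on white data is ~1/sqrt(n)
  expect_lt(max(abs(off)), 3 * 1.5 / sqrt(20000))
})

test_that("order selection by BIC finds the generating order", {
  m <- random_stable_mvar(3, 3, seed = 24)
  rec <- simulate_mvar(m, 15000, seed = 3)
  fit <- fit_mvar(rec, order = "auto", p_max = 8)
  expect_equal(fit$p, 3L)
  expect_error(fit_mvar(rec, order = 0), "order")
})

test_that("the spectral transfer matrix matches hand evaluation", {
  m0 <- mvar_model(array(0.5, c(1, 1, 1)), matrix(1), 500)
  expect_equal(spectral_transfer(m0, 125)[1, 1, 1], 1 + 0.5i)
  m <- random_stable_mvar(3, 2, seed = 25)
  A0 <- spectral_transfer(m, 0)[, , 1]
  expect_equal(Re(A0), diag(3) - m$A[, , 1] - m$A[, , 2], tolerance = 1e-12)
  expect_equal(max(abs(Im(A0))), 0)
  null_m <- mvar_model(array(0, c(2, 2, 3)), diag(2), 500)
  for (f in c(0, 10, 100))
    expect_equal(spectral_transfer(null_m, f)[, , 1], diag(2) + 0i)
})

test_that("gPDC obeys its normalization identity and hand formula", {
  m <- random_stable_mvar(4, 3, seed = 26, sd = 0.15)
  m$Sigma <- diag(c(1, 4, 0.25, 2))
  g <- gpdc(m)
  cn <- apply(g$pi_abs^2, c(2, 3), sum)
  expect_lt(max(abs(cn - 1)), 1e-10)
  expect_true(all(g$pi_abs >= 0 & g$pi_abs <= 1))
  for (f in c(1, 25.5, 80)) {
    fi <- which(g$freqs == f)
    expect_equal(g$pi_abs[2, 3, fi],
                 gpdc_by_hand(m$A, m$Sigma, 500, 2, 3, f), tolerance = 1e-12)
  }
})

test_that("uncoupled regions have zero gPDC; unidirectional stays one-way", {
  diag_m <- mvar_model(array(c(0.5, 0, 0, 0.3), c(2, 2, 1)), diag(2), 500)
  g <- gpdc(diag_m)
  expect_equal(max(g$pi_abs[1, 2, ]), 0)
  expect_equal(max(g$pi_abs[2, 1, ]), 0)
  A <- array(0, c(2, 2, 1)); A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.5
  A[1, 2, 1] <- 0.4
  uni <- mvar_model(A, diag(2), 500)
  gu <- gpdc(uni)
  expect_true(all(gu$pi_abs[1, 2, ] > 0))
  expect_equal(max(gu$pi_abs[2, 1, ]), 0)
  # hand evaluation at f = 0: Abar = [[0.5, -0.4], [0, 0.5]]
  expect_equal(gu$pi_abs[1, 2, gu$freqs == 1][1],
               gpdc_by_hand(A, diag(2), 500, 1, 2, 1), tolerance = 1e-12)
  expect_error(gpdc(mvar_model(A, matrix(c(0, 0, 0, 1), 2), 500)),
               "innovation variance")
})

test_that("gPDC sparsity pattern is invariant to channel rescaling", {
  m <- random_stable_mvar(3, 2, seed = 27)
  m$A[2, 3, ] <- 0; m$A[3, 2, ] <- 0      # cut the 2<->3 coupling
  g1 <- gpdc(m)
  a <- 4
  m2 <- m
  m2$A[1, , ] <- m$A[1, , ] ; m2$A[, 1, ] <- m$A[, 1, ]
  m2$A[1, -1, ] <- a * m$A[1, -1, ]       # channel 1 data scaled by a
  m2$A[-1, 1, ] <- m$A[-1, 1, ] / a
  m2$Sigma <- m$Sigma; m2$Sigma[1, 1] <- a^2 * m$Sigma[1, 1]
  g2 <- gpdc(m2)
  expect_equal(g1$pi_abs > 1e-12, g2$pi_abs > 1e-12)
})

test_that("band means of gPDC average the grid and respect the region set", {
  g <- structure(list(
    freqs = seq(1, 100, 0.5),
    pi_abs = array(0.3, c(3, 3, 199)),
    labels = c("X", "Y", "Z")), class = "gpdc_spectrum")
  bm <- band_mean_gpdc(g, 21, 30)
  expect_equal(unique(bm$gpdc), 0.3)
  expect_equal(nrow(bm), 6)
  expect_false(any(bm$src == bm$dst))
  bm2 <- band_mean_gpdc(g, 21, 30, regions = c("X", "Z"))
  expect_equal(nrow(bm2), 2)
  expect_error(band_mean_gpdc(g, 200, 220), "grid points")
})

test_that("reverse-direction gPDC stays below the phase-randomized null", {
  A <- array(0, c(2, 2, 1)); diag(A[, , 1]) <- 0.5; A[1, 2, 1] <- 0.4
  m <- mvar_model(A, diag(2), 500, labels = c("tgt", "drv"))
  rec <- simulate_mvar(m, 10000, seed = 31)
  bm <- function(r) {
    g <- gpdc(fit_mvar(r, order = 1))
    b <- band_mean_gpdc(g, 21, 30)
    b$gpdc[b$src == "tgt" & b$dst == "drv"]
  }
  rev_obs <- bm(rec)
  null_rev <- vapply(1:49, function(i) bm(phase_randomize(rec, seed = 100 + i)),
                     numeric(1))
  expect_lt(rev_obs, quantile(null_rev, 0.95))
})

test_that("connectivity tables track the designed level modulation", {
  net <- default_network_spec()
  set.seed(41)
  recs <- lapply(0:3, function(l)
    simulate_mvar(build_mvar_from_spec(net, l), 20000))
  names(recs) <- 0:3
  tab <- connectivity_table(recs, order = 16,
                            regions = c("M1", "SMA", "DPMC", "VPMC", "STN"))
  hb <- tab[tab$band == "high_beta" & tab$src == "STN" & tab$dst == "M1", ]
  expect_true(all(diff(hb$gpdc[order(hb$level)]) < 0))
  hg <- tab[tab$band == "high_gamma" & tab$src == "SMA" & tab$dst == "M1", ]
  expect_true(all(diff(hg$gpdc[order(hg$level)]) > 0))
  expect_true(all(tab$gpdc >= 0 & tab$gpdc <= 1))
})
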