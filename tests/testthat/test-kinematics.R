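test_that("tangential velocity matches the generator's closed form", {
  cfg <- spiral_gen_config()
  tr <- gen_spiral(cfg, 0)
  v <- tangential_velocity(tr)
  v_true <- (cfg$spacing_cm / (2 * pi)) * tr$meta$omega^2 * tr$t
  rel <- abs(v[-(1:3)] - v_true[-(1:3)]) / pmax(v_true[-(1:3)], 1e-9)
  expect_lt(max(rel), 0.01)
})

test_that("a pure circle gives constant tangential velocity R*omega", {
  R <- 2; om <- 1.5; t <- seq(0, 10, by = 0.01)
  # centre supplied explicitly: the trace never visits the centre itself
  tr <- spiral_trace(t, R * cos(om * t), R * sin(om * t))
  v <- tangential_velocity(tr, center = c(0, 0))
  expect_equal(v[5:(length(v) - 5)],
               rep(R * om, length(v) - 9), tolerance = 1e-6)
})

test_that("velocity is invariant under rotation and direction-normalized", {
  cfg <- spiral_gen_config(entropy_knob = 0.2)
  tr <- gen_spiral(cfg, 2, seed = 3)
  v <- tangential_velocity(tr)
  expect_true(all(v[-1] >= -1e-9))
  a <- 0.7  # rotate about the first sample
  cx <- tr$x[1]; cy <- tr$y[1]
  rot <- tr
  rot$x <- cx + cos(a) * (tr$x - cx) - sin(a) * (tr$y - cy)
  rot$y <- cy + sin(a) * (tr$x - cx) + cos(a) * (tr$y - cy)
  # the first samples sit at the degenerate centre (angle undefined there)
  keep <- -(1:3)
  expect_equal(tangential_velocity(rot)[keep], v[keep], tolerance = 1e-10)
  cw <- gen_spiral(spiral_gen_config(entropy_knob = 0.2,
                                     direction = "clockwise"), 2, seed = 3)
  expect_equal(tangential_velocity(cw)[keep], v[keep], tolerance = 1e-10)
})

test_that("a stationary pen is a degenerate radius error", {
  tr <- spiral_trace(0:9 / 10, rep(1, 10), rep(2, 10))
  expect_error(tangential_velocity(tr), "degenerate radius")
})

test_that("position derivatives are exact on polynomials and bounded on sines", {
  t <- seq(0, 5, by = 0.01)
  tr <- spiral_trace(t, t^2, 3 * t^2 - t)
  d <- position_derivatives(tr)
  expect_equal(d$d1[, "x"], 2 * t, tolerance = 1e-8)
  expect_equal(d$d2[, "x"], rep(2, length(t)), tolerance = 1e-8)
  expect_equal(d$d3[, "y"], rep(0, length(t)), tolerance = 1e-6)
  # constant trace: all derivatives zero (constant x; linear y keeps t valid)
  trc <- spiral_trace(t, rep(1, length(t)), t)
  dc <- position_derivatives(trc)
  expect_equal(max(abs(dc$d1[, "x"])), 0)
  expect_equal(max(abs(dc$d2)), 0, tolerance = 1e-10)
  # Taylor bound for a sine: central-difference error <= (2 pi f)^3 dt^2 / 6
  f <- 2; fs <- 100; ts <- seq(0, 3, by = 1 / fs)
  trs <- spiral_trace(ts, sin(2 * pi * f * ts), ts)
  ds <- position_derivatives(trs)
  err <- abs(ds$d1[, "x"] - 2 * pi * f * cos(2 * pi * f * ts))
  inner <- 2:(length(ts) - 1)
  expect_lt(max(err[inner]), (2 * pi * f)^3 * (1 / fs)^2 / 6 * 1.01)
})

test_that("sample entropy equals the exhaustive O(N^2) oracle exactly", {
  set.seed(14)
  for (x in list(rnorm(120), as.numeric(1:100), sin(1:150 / 5) + rnorm(150, sd = 0.1),
                 rep(c(1, 5), 60))) {
    expect_identical(sample_entropy(x), sampen_bruteforce(x))
  }
})

test_that("sample entropy is affine-invariant, zero for constants, monotone in r", {
  set.seed(15)
  x <- rnorm(200)
  expect_equal(sample_entropy(-3.2 * x + 40), sample_entropy(x))
  expect_equal(sample_entropy(rep(7, 50)), 0)
  rs <- c(0.1, 0.2, 0.4, 0.8)
  vals <- vapply(rs, function(r) sample_entropy(x, r_frac = r), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("undefined sample entropy is flagged, not infinite", {
  # strictly exponential growth: no template pairs match at tiny tolerance
  x <- 2^(1:40)
  expect_warning(v <- sample_entropy(x, r_frac = 1e-12), "undefined")
  expect_true(is.na(v))
})

test_that("level summaries average the per-spiral parameters", {
  cfg <- spiral_gen_config(entropy_knob = 0.2, n_loops = 2,
                           base_angular_speed = 2 * pi * 2 / 6)
  traces <- lapply(1:5, function(r)
    gen_spiral(cfg, 1, rep = r, seed = 20 + r))
  s <- summarize_level(traces)
  per_mean <- mean(vapply(traces, function(tr)
    mean(tangential_velocity(tr)), numeric(1)))
  expect_equal(s$mean_velocity, per_mean)
  expect_gte(s$peak_velocity, s$mean_velocity)
  expect_equal(s$n_spirals_averaged, 5L)
  # five identical traces collapse to the single-trace values
  same <- lapply(1:5, function(r) { tr <- traces[[1]]; tr$rep <- r; tr })
  s1 <- summarize_level(same)
  expect_equal(s1$mean_velocity, mean(tangential_velocity(traces[[1]])))
  expect_error(summarize_level(list()), "empty")
  mixed <- traces; mixed[[2]]$level <- 3L
  expect_error(summarize_level(mixed), "share")
})

test_that("slope across levels is plain OLS on the level index", {
  expect_equal(slope_across_levels(c(1, 2, 3, 4)),
               list(slope = 1, intercept = 1, levels = 0:3),
               tolerance = 1e-12)
  expect_equal(slope_across_levels(c(5, 5, 5, 5))$slope, 0)
  expect_equal(slope_across_levels(c(0, 1, 1, 2))$slope, 0.6)
  expect_equal(slope_across_levels(c(2, NA, NA, 3))$slope, 1 / 3)
  expect_error(slope_across_levels(c(1, NA, NA, NA)), "2 levels")
})
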