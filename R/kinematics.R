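# Gradient with 3-point one-sided boundary formulas; exact for quadratics on
# a uniform grid, per-interval dt handles mildly non-uniform time stamps.
.gradient <- function(y, t) {
  n <- length(y)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  g <- numeric(n)
  dt1 <- t[2:(n - 1)] - t[1:(n - 2)]
  dt2 <- t[3:n] - t[2:(n - 1)]
  # non-uniform central difference
  g[2:(n - 1)] <- (y[3:n] * dt1^2 + (dt2^2 - dt1^2) * y[2:(n - 1)] -
                     y[1:(n - 2)] * dt2^2) / (dt1 * dt2 * (dt1 + dt2))
  h1 <- t[2] - t[1]; h2 <- t[3] - t[2]
  g[1] <- (-(2 * h1 + h2) / (h1 * (h1 + h2))) * y[1] +
    ((h1 + h2) / (h1 * h2)) * y[2] - (h1 / (h2 * (h1 + h2))) * y[3]
  h1 <- t[n - 1] - t[n - 2]; h2 <- t[n] - t[n - 1]
  g[n] <- (h2 / (h1 * (h1 + h2))) * y[n - 2] -
    ((h1 + h2) / (h1 * h2)) * y[n - 1] +
    ((h1 + 2 * h2) / (h2 * (h1 + h2))) * y[n]
  g
}

#' First three derivatives of pen position
#'
#' Central finite differences on the interior, second-order one-sided stencils
#' at the boundaries; repeated application yields the second and third
#' derivatives. Non-uniform time stamps are handled with per-interval spacing.
#'
#' @param trace a [spiral_trace()] with >= 4 samples.
#' @return list with matrices `d1`, `d2`, `d3` (columns `x`, `y`), units
#'   cm/s, cm/s^2, cm/s^3.
#' @export
position_derivatives <- function(trace) {
  stopifnot(inherits(trace, "spiral_trace"))
  if (length(trace$t) < 4L) stop("need at least 4 samples")
  t <- trace$t
  d1 <- cbind(x = .gradient(trace$x, t), y = .gradient(trace$y, t))
  d2 <- cbind(x = .gradient(d1[, "x"], t), y = .gradient(d1[, "y"], t))
  d3 <- cbind(x = .gradient(d2[, "x"], t), y = .gradient(d2[, "y"], t))
  list(d1 = d1, d2 = d2, d3 = d3)
}

#' Tangential velocity of a spiral trace
#'
#' The pen's linear velocity along its circular path: the rate of change of
#' the (unwrapped) angular displacement around the spiral centre multiplied by
#' the instantaneous radius. The centre defaults to the first recorded sample,
#' matching the instruction to start drawing from the centre. The sign of the
#' net rotation is normalized away so the series is non-negative for a
#' monotone drawing in either direction.
#'
#' @param trace a [spiral_trace()].
#' @param center optional c(x, y) centre; defaults to the first sample.
#' @return numeric vector of tangential velocity (cm/s), one value per sample.
#' @export
tangential_velocity <- function(trace, center = NULL) {
  stopifnot(inherits(trace, "spiral_trace"))
  if (is.null(center)) center <- c(trace$x[1L], trace$y[1L])
  dx <- trace$x - center[1L]
  dy <- trace$y - center[2L]
  r <- sqrt(dx^2 + dy^2)
  if (max(r) < .Machine$double.eps^0.5)
    stop("degenerate radius: all samples at the centre point")
  phi <- atan2(dy, dx)
  dphi <- diff(phi)
  dphi <- ((dphi + pi) %% (2 * pi)) - pi   # signed increments in (-pi, pi]
  theta <- cumsum(c(0, dphi))              # unwrapped angle
  dtheta_dt <- .gradient(theta, trace$t)
  dir <- sign(theta[length(theta)] - theta[1L])
  if (dir == 0) dir <- 1
  r * dtheta_dt * dir
}

#' Sample entropy of a time series
#'
#' SampEn(m, r) = -ln(A/B), where B counts pairs of length-`m` templates and
#' A pairs of length-`m+1` templates whose Chebyshev distance is at most
#' r = `r_frac` * SD(series); self-matches are excluded and both counts run
#' over the first N-m template start points (Richman-Moorman convention).
#' Because r scales with the series SD, SampEn is invariant under affine
#' transforms of the data. A constant series yields A = B and SampEn = 0.
#'
#' @param series numeric vector, length > m+1.
#' @param m template length (default 2).
#' @param r_frac tolerance as a fraction of the series SD (default 0.2).
#' @return the entropy value; `NA` (flagged undefined, with a warning) when
#'   no template pairs match at length m or m+1.
#' @export
sample_entropy <- function(series, m = 2L, r_frac = 0.2) {
  series <- as.numeric(series)
  n <- length(series)
  if (anyNA(series)) stop("series contains NA")
  if (n <= m + 1L) stop("series too short for the requested template length")
  r <- r_frac * stats::sd(series)
  nt <- n - m                      # template start points used for both counts
  # Chebyshev distance between m-templates, built up one embedding lag at a time
  dmax <- abs(outer(series[1:nt], series[1:nt], "-"))
  for (k in seq_len(m - 1L)) {
    idx <- (1:nt) + k
    dk <- abs(outer(series[idx], series[idx], "-"))
    dmax <- pmax(dmax, dk)
  }
  B <- (sum(dmax <= r) - nt) / 2    # exclude self-matches, unordered pairs
  idx <- (1:nt) + m
  dmax <- pmax(dmax, abs(outer(series[idx], series[idx], "-")))
  A <- (sum(dmax <= r) - nt) / 2
  if (A == 0 || B == 0) {
    warning("sample entropy undefined: no matching templates")
    return(NA_real_)
  }
  -log(A / B)
}

#' Kinematic summary of the spirals drawn under one condition
#'
#' Computes mean and peak tangential velocity and the sample entropy of the
#' velocity series per spiral, then averages the parameters over the spirals
#' (typically five) drawn by one subject in one task at one stimulation
#' level. Undefined entropies are dropped from the average with a warning.
#'
#' @param traces list of [spiral_trace()] objects sharing subject, task and
#'   level.
#' @param m,r_frac sample-entropy parameters, see [sample_entropy()].
#' @return a one-row data.frame: subject, task, level, mean_velocity,
#'   peak_velocity, velocity_sampen, n_spirals_averaged.
#' @export
summarize_level <- function(traces, m = 2L, r_frac = 0.2) {
  if (!length(traces)) stop("empty set of traces")
  stopifnot(all(vapply(traces, inherits, logical(1), "spiral_trace")))
  key <- vapply(traces, function(tr) paste(tr$subject, tr$task, tr$level),
                character(1))
  if (length(unique(key)) != 1L)
    stop("all traces must share subject, task and stimulation level")
  per <- vapply(traces, function(tr) {
    v <- tangential_velocity(tr)
    c(mean(v), max(v), sample_entropy(v, m = m, r_frac = r_frac))
  }, numeric(3))
  tr1 <- traces[[1L]]
  data.frame(
    subject = tr1$subject, task = tr1$task, level = tr1$level,
    mean_velocity = mean(per[1, ]),
    peak_velocity = mean(per[2, ]),
    velocity_sampen = mean(per[3, ], na.rm = TRUE),
    n_spirals_averaged = length(traces),
    stringsAsFactors = FALSE
  )
}

#' Least-squares slope of a parameter across stimulation levels
#'
#' Ordinary least squares of the parameter value on the ordinal level index
#' (0, 1, 2, 3); the per-level step is the within-subject design variable.
#'
#' @param values named or ordered numeric vector, one value per level;
#'   `NA` levels are dropped.
#' @param levels level indices matching `values` (default `0:3` truncated).
#' @return list with `slope`, `intercept`, `levels` used.
#' @export
slope_across_levels <- function(values, levels = NULL) {
  values <- as.numeric(values)
  if (is.null(levels)) levels <- seq_along(values) - 1
  keep <- !is.na(values)
  values <- values[keep]; levels <- levels[keep]
  if (length(values) < 2L) stop("need at least 2 levels to fit a slope")
  lx <- levels - mean(levels)
  slope <- sum(lx * (values - mean(values))) / sum(lx^2)
  list(slope = slope, intercept = mean(values) - slope * mean(levels),
       levels = levels)
}
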