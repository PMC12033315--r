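#' Multivariate autoregressive model
#'
#' x_t = sum_r A_r x_{t-r} + e_t with innovation covariance Sigma. This is
#' both the generative object behind the synthetic recordings and the fitted
#' object from which generalized partial directed coherence is computed.
#'
#' @param A numeric array K x K x p; `A[i, j, r]` is the influence of region
#'   j at lag r on region i.
#' @param Sigma innovation covariance (K x K, positive semi-definite).
#' @param fs_hz sampling rate the lags refer to.
#' @param labels optional region labels.
#' @return an `mvar_model` object.
#' @export
mvar_model <- function(A, Sigma, fs_hz, labels = NULL) {
  if (length(dim(A)) == 2L) A <- array(A, dim = c(dim(A), 1L))
  stopifnot(length(dim(A)) == 3L, dim(A)[1] == dim(A)[2])
  K <- dim(A)[1]
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == K, ncol(Sigma) == K)
  if (any(abs(Sigma - t(Sigma)) > 1e-10)) stop("Sigma must be symmetric")
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("Sigma must be positive semi-definite")
  if (is.null(labels)) labels <- paste0("roi", seq_len(K))
  structure(list(A = A, Sigma = Sigma, fs_hz = fs_hz,
                 labels = as.character(labels), p = dim(A)[3], K = K),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> K=%d regions, order p=%d, fs=%g Hz, spectral radius %.3f\n",
              x$K, x$p, x$fs_hz, mvar_spectral_radius(x)))
  invisible(x)
}

#' Companion-matrix spectral radius of an MVAR model
#'
#' The process is (weakly) stationary iff the radius is < 1.
#'
#' @param model an [mvar_model()].
#' @return the largest eigenvalue modulus of the companion matrix.
#' @export
mvar_spectral_radius <- function(model) {
  K <- model$K; p <- model$p
  comp <- matrix(0, K * p, K * p)
  comp[1:K, ] <- matrix(model$A, K, K * p)
  if (p > 1L)
    comp[(K + 1):(K * p), 1:(K * (p - 1))] <- diag(K * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Is the MVAR model stable?
#' @param model an [mvar_model()].
#' @param tol stability margin (radius must be below `1 - tol`).
#' @return logical.
#' @export
mvar_is_stable <- function(model, tol = 1e-8) {
  mvar_spectral_radius(model) < 1 - tol
}

#' Band-selective coupling kernel over lags
#'
#' Designs a short real lag kernel c_1..c_L whose frequency response has unit
#' magnitude (linear phase) at the coupling band centre and minimal energy
#' over a stop band, by equality-constrained least squares. Used so that a
#' directed edge injected into an MVAR model carries power essentially only
#' in its own band: a beta edge then leaves gamma-band directed coherence
#' untouched and vice versa.
#'
#' @param f0_hz band centre of the coupling (Hz).
#' @param fs_hz sampling rate (Hz).
#' @param n_lags kernel length L (model order of the generator).
#' @param stop_lo,stop_hi stop band to suppress (Hz).
#' @param ridge small Tikhonov term keeping coefficients bounded.
#' @return numeric vector of length `n_lags`.
#' @export
design_band_kernel <- function(f0_hz, fs_hz, n_lags = 16L,
                               stop_lo, stop_hi, ridge = 1e-6) {
  stopifnot(n_lags >= 3L, f0_hz > 0, stop_hi > stop_lo)
  r <- seq_len(n_lags)
  # stop-band energy: integral over the band of |C(f)|^2, C(f)=sum c_r e^{-i w r}
  fgrid <- seq(stop_lo, stop_hi, length.out = 256L)
  wgrid <- 2 * pi * fgrid / fs_hz
  Q <- matrix(0, n_lags, n_lags)
  for (a in r) for (b in r)
    Q[a, b] <- mean(cos(wgrid * (a - b)))
  w0 <- 2 * pi * f0_hz / fs_hz
  m <- (n_lags + 1) / 2                       # linear-phase target delay
  Amat <- rbind(cos(w0 * r), -sin(w0 * r))    # Re and Im of C(f0)
  bvec <- c(cos(w0 * m), -sin(w0 * m))
  KKT <- rbind(cbind(2 * (Q + ridge * diag(n_lags)), t(Amat)),
               cbind(Amat, matrix(0, 2, 2)))
  sol <- solve(KKT, c(rep(0, n_lags), bvec))
  sol[r]
}

#' Specification of a synthetic stimulation-modulated brain network
#'
#' Each region of interest is a damped AR(2) resonator (complex-conjugate
#' poles at radius `damping`, angle 2*pi*f0/fs); directed edges couple the
#' regions through band-selective lag kernels. Edge gains and innovation SDs
#' are modulated multiplicatively by the stimulation level (0..3), which is
#' how the generator emulates stimulation-dependent connectivity and power:
#' high-beta subthalamo-cortical edges weaken with level while high-gamma
#' premotor-to-M1 edges strengthen.
#'
#' @param roi_labels ordered region names.
#' @param oscillators data.frame with one row per ROI: `f0_hz` (resonance),
#'   `damping` (pole radius in (0,1)), `sigma0` (innovation SD at level 0),
#'   `sigma_level_slope` (fractional SD change per level step).
#' @param edges data.frame with columns `src`, `dst`, `f0_hz`, `gain`,
#'   `level_slope` (fractional gain change per level), `stop_lo`, `stop_hi`
#'   (band suppressed by the kernel). May have zero rows.
#' @param fs_hz simulation rate (Hz).
#' @param kernel_length lag-kernel length (also the model order when edges
#'   are present).
#' @return a `network_spec` object.
#' @export
network_spec <- function(roi_labels, oscillators, edges = NULL, fs_hz = 500,
                         kernel_length = 16L) {
  stopifnot(length(roi_labels) >= 1, !anyDuplicated(roi_labels))
  oscillators <- as.data.frame(oscillators)
  stopifnot(nrow(oscillators) == length(roi_labels),
            all(c("f0_hz", "damping", "sigma0") %in% names(oscillators)))
  if (is.null(oscillators$sigma_level_slope)) oscillators$sigma_level_slope <- 0
  stopifnot(all(oscillators$damping > 0), all(oscillators$damping < 1),
            all(oscillators$sigma0 > 0))
  if (is.null(edges)) {
    edges <- data.frame(src = character(), dst = character(), f0_hz = numeric(),
                        gain = numeric(), level_slope = numeric(),
                        stop_lo = numeric(), stop_hi = numeric())
  }
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    stopifnot(all(edges$src %in% roi_labels), all(edges$dst %in% roi_labels),
              all(is.finite(edges$gain)))
    if (any(edges$src == edges$dst)) stop("self-edges are not allowed")
  }
  structure(list(roi_labels = as.character(roi_labels),
                 oscillators = oscillators, edges = edges,
                 fs_hz = fs_hz, kernel_length = as.integer(kernel_length)),
            class = "network_spec")
}

#' The default stimulation-modulated motor network
#'
#' Five-region network {STN, M1, SMA, DPMC, VPMC}: STN and M1 resonate in the
#' high-beta band (25 Hz), the premotor regions in the high-gamma band
#' (80 Hz). Bidirectional 25 Hz STN-M1 edges weaken by 25% per stimulation
#' level (hyperdirect-pathway suppression); 80 Hz premotor-to-M1 and
#' M1-to-premotor edges strengthen by 50% of their base gain per level
#' (cortico-cortical gamma facilitation). STN/M1 innovation SDs fall and the
#' premotor SDs rise slightly with level, giving the band-power table its
#' level trends.
#'
#' @param fs_hz simulation rate.
#' @param include_extra if `TRUE`, adds the three level-neutral reference
#'   regions pre-SMA, DLPFC (beta resonators, mildly level-decreasing power)
#'   and VC (10 Hz resonator, level-invariant) used by the power and
#'   prediction stages, completing the standard eight-ROI motor montage.
#' @return a [network_spec()].
#' @export
default_network_spec <- function(fs_hz = 500, include_extra = FALSE) {
  rois <- c("STN", "M1", "SMA", "DPMC", "VPMC")
  osc <- data.frame(
    f0_hz = c(25, 25, 80, 80, 80),
    damping = c(0.85, 0.85, 0.85, 0.85, 0.85),
    sigma0 = c(1, 1, 1, 1, 1),
    sigma_level_slope = c(-0.12, -0.12, 0.08, 0.08, 0.08)
  )
  if (include_extra) {
    rois <- c(rois, "preSMA", "DLPFC", "VC")
    osc <- rbind(osc, data.frame(
      f0_hz = c(25, 25, 10), damping = c(0.85, 0.85, 0.9),
      sigma0 = c(1, 1, 1), sigma_level_slope = c(-0.08, -0.12, 0)
    ))
  }
  beta_stop <- c(55, 110); gamma_stop <- c(10, 35)
  edges <- rbind(
    data.frame(src = "STN", dst = "M1", f0_hz = 25, gain = 0.04,
               level_slope = -0.25, stop_lo = beta_stop[1], stop_hi = beta_stop[2]),
    data.frame(src = "M1", dst = "STN", f0_hz = 25, gain = 0.04,
               level_slope = -0.25, stop_lo = beta_stop[1], stop_hi = beta_stop[2]),
    data.frame(src = "SMA", dst = "M1", f0_hz = 80, gain = 0.10,
               level_slope = 0.5, stop_lo = gamma_stop[1], stop_hi = gamma_stop[2]),
    data.frame(src = "DPMC", dst = "M1", f0_hz = 80, gain = 0.10,
               level_slope = 0.5, stop_lo = gamma_stop[1], stop_hi = gamma_stop[2]),
    data.frame(src = "VPMC", dst = "M1", f0_hz = 80, gain = 0.10,
               level_slope = 0.5, stop_lo = gamma_stop[1], stop_hi = gamma_stop[2]),
    data.frame(src = "M1", dst = "SMA", f0_hz = 80, gain = 0.10,
               level_slope = 0.5, stop_lo = gamma_stop[1], stop_hi = gamma_stop[2])
  )
  network_spec(rois, osc, edges, fs_hz = fs_hz)
}

#' Build the MVAR model realized by a network spec at one stimulation level
#'
#' Diagonal blocks are the AR(2) resonators; every edge adds its
#' band-selective lag kernel, scaled by `gain * max(0, 1 + level_slope *
#' level)`, to the (dst, src) cross-coefficients. Innovation SDs are scaled
#' by `max(0.05, 1 + sigma_level_slope * level)`. The construction is
#' rejected if the resulting model is unstable, naming the offending edge.
#'
#' @param spec a [network_spec()].
#' @param level stimulation level 0..3.
#' @return a stable [mvar_model()].
#' @export
build_mvar_from_spec <- function(spec, level = 0) {
  stopifnot(inherits(spec, "network_spec"), level %in% 0:3)
  K <- length(spec$roi_labels)
  p <- if (nrow(spec$edges)) max(2L, spec$kernel_length) else 2L
  A <- array(0, dim = c(K, K, p))
  for (i in seq_len(K)) {
    th <- 2 * pi * spec$oscillators$f0_hz[i] / spec$fs_hz
    rho <- spec$oscillators$damping[i]
    A[i, i, 1] <- 2 * rho * cos(th)
    A[i, i, 2] <- -rho^2
  }
  if (nrow(spec$edges)) {
    for (e in seq_len(nrow(spec$edges))) {
      ed <- spec$edges[e, ]
      g <- ed$gain * max(0, 1 + ed$level_slope * level)
      if (g == 0) next
      kern <- design_band_kernel(ed$f0_hz, spec$fs_hz, spec$kernel_length,
                                 ed$stop_lo, ed$stop_hi)
      di <- match(ed$dst, spec$roi_labels)
      si <- match(ed$src, spec$roi_labels)
      A[di, si, seq_len(spec$kernel_length)] <-
        A[di, si, seq_len(spec$kernel_length)] + g * kern
    }
  }
  sig <- spec$oscillators$sigma0 *
    pmax(0.05, 1 + spec$oscillators$sigma_level_slope * level)
  model <- mvar_model(A, diag(sig^2, K), spec$fs_hz, spec$roi_labels)
  if (!mvar_is_stable(model)) {
    # identify an edge whose removal restores stability, for the error message
    culprit <- "(unknown)"
    for (e in seq_len(nrow(spec$edges))) {
      sp2 <- spec; sp2$edges <- spec$edges[-e, ]
      if (mvar_is_stable(build_try(sp2, level))) {
        culprit <- sprintf("%s->%s (gain %.3g)", spec$edges$src[e],
                           spec$edges$dst[e], spec$edges$gain[e])
        break
      }
    }
    stop(sprintf("unstable MVAR construction; offending edge: %s", culprit))
  }
  model
}

# like build_mvar_from_spec but never errors on instability (internal)
build_try <- function(spec, level) {
  m <- try(suppressWarnings(build_mvar_from_spec(spec, level)), silent = TRUE)
  if (inherits(m, "try-error")) return(mvar_model(array(2, c(1, 1, 1)), 1, spec$fs_hz))
  m
}

#' Simulate a stationary realization of an MVAR model
#'
#' Starts from zeros, discards a burn-in of `10 * p` samples, and returns a
#' source-space recording. Innovations are Gaussian with covariance Sigma.
#'
#' @param model a stable [mvar_model()].
#' @param n_samples samples to return after burn-in.
#' @param seed optional RNG seed.
#' @param burn_in burn-in length (default `10 * p`).
#' @return an [mc_recording()] in source space.
#' @export
simulate_mvar <- function(model, n_samples, seed = NULL,
                          burn_in = 10L * model$p) {
  stopifnot(inherits(model, "mvar_model"), n_samples > 0)
  if (!mvar_is_stable(model))
    stop("refusing to simulate an unstable MVAR model")
  if (!is.null(seed)) set.seed(seed)
  K <- model$K; p <- model$p
  Tn <- n_samples + burn_in + p
  if (all(model$Sigma == 0)) {
    E <- matrix(0, K, Tn)
  } else {
    cS <- chol(model$Sigma + 1e-14 * mean(diag(model$Sigma)) * diag(K))
    E <- t(cS) %*% matrix(stats::rnorm(K * Tn), K, Tn)
  }
  B <- matrix(model$A, K, K * p)      # [A_1 | A_2 | ... | A_p]
  X <- matrix(0, K, Tn)
  for (t in (p + 1):Tn) {
    X[, t] <- E[, t] + B %*% as.vector(X[, t - seq_len(p), drop = FALSE])
  }
  mc_recording(X[, (p + burn_in + 1):Tn, drop = FALSE], model$fs_hz,
               labels = model$labels, space = "source")
}

#' Sensor model for the synthetic forward projection
#'
#' @param n_sensors electrode count (default 64).
#' @param sensor_noise_sd additive white sensor noise SD.
#' @param line_noise_amp amplitude of 50 Hz line contamination (0 disables).
#' @param dbs_rate_hz,dbs_amp,dbs_duty rectangular stimulation pulse train:
#'   pulse rate (~130-135 Hz in chronic stimulators), amplitude (0 disables)
#'   and duty cycle.
#' @param leadfield_seed seed for lead-field generation.
#' @return a `sensor_model_spec` list.
#' @export
sensor_model_spec <- function(n_sensors = 64L, sensor_noise_sd = 0.5,
                              line_noise_amp = 0, dbs_rate_hz = 130,
                              dbs_amp = 0, dbs_duty = 0.2,
                              leadfield_seed = 42L) {
  stopifnot(n_sensors >= 1, sensor_noise_sd >= 0, line_noise_amp >= 0,
            dbs_amp >= 0, dbs_duty > 0, dbs_duty < 1)
  structure(list(n_sensors = as.integer(n_sensors),
                 sensor_noise_sd = sensor_noise_sd,
                 line_noise_amp = line_noise_amp, dbs_rate_hz = dbs_rate_hz,
                 dbs_amp = dbs_amp, dbs_duty = dbs_duty,
                 leadfield_seed = as.integer(leadfield_seed)),
            class = "sensor_model_spec")
}

#' Generate a smooth random lead field
#'
#' Gaussian random mixing smoothed across the sensor index (mimicking spatial
#' spread of volume conduction without anatomy), columns normalized to unit
#' norm. Regenerated up to `max_tries` times if rank-deficient.
#'
#' @param n_sensors,n_sources dimensions (sensors >= sources).
#' @param source_labels,sensor_labels optional label vectors.
#' @param seed RNG seed.
#' @param smooth_sd Gaussian smoothing SD in sensor-index units.
#' @param max_tries retries on rank deficiency.
#' @return a `lead_field` object: `matrix` (sensors x sources),
#'   `source_labels`, `sensor_labels`.
#' @export
make_leadfield <- function(n_sensors, n_sources, source_labels = NULL,
                           sensor_labels = NULL, seed = 42L, smooth_sd = 3,
                           max_tries = 5L) {
  if (n_sensors < n_sources) stop("need at least as many sensors as sources")
  if (is.null(source_labels)) source_labels <- paste0("src", seq_len(n_sources))
  if (is.null(sensor_labels)) sensor_labels <- sprintf("E%02d", seq_len(n_sensors))
  set.seed(seed)
  W <- stats::dnorm(outer(seq_len(n_sensors), seq_len(n_sensors), "-"),
                    sd = smooth_sd)
  W <- W / rowSums(W)
  for (tr in seq_len(max_tries)) {
    G <- W %*% matrix(stats::rnorm(n_sensors * n_sources), n_sensors, n_sources)
    G <- sweep(G, 2L, sqrt(colSums(G^2)), "/")
    if (qr(G)$rank == n_sources)
      return(structure(list(matrix = G, source_labels = source_labels,
                            sensor_labels = sensor_labels),
                       class = "lead_field"))
  }
  stop("failed to generate a full-column-rank lead field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d sensors x %d sources\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Project source activity to the sensor array
#'
#' sensors = L * sources + white noise + 50 Hz line noise + optional
#' rectangular stimulation pulse train (projected through a random smooth
#' topography). The lead field used is returned for the beamformer.
#'
#' @param sources an [mc_recording()] in source space.
#' @param sensor_spec a [sensor_model_spec()].
#' @param leadfield optional [make_leadfield()] result; generated from
#'   `sensor_spec$leadfield_seed` when missing.
#' @param seed RNG seed for the noise terms.
#' @return list with `recording` (sensor space) and `leadfield`.
#' @export
project_to_sensors <- function(sources, sensor_spec, leadfield = NULL,
                               seed = NULL) {
  stopifnot(inherits(sources, "mc_recording"), sources$space == "source",
            inherits(sensor_spec, "sensor_model_spec"))
  K <- nrow(sources$data)
  if (sensor_spec$n_sensors < K)
    stop("need at least as many sensors as sources")
  if (is.null(leadfield)) {
    leadfield <- make_leadfield(sensor_spec$n_sensors, K,
                                source_labels = sources$labels,
                                seed = sensor_spec$leadfield_seed)
  }
  stopifnot(inherits(leadfield, "lead_field"),
            ncol(leadfield$matrix) == K,
            nrow(leadfield$matrix) == sensor_spec$n_sensors)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(sources$data)
  Y <- leadfield$matrix %*% sources$data
  if (sensor_spec$sensor_noise_sd > 0)
    Y <- Y + matrix(stats::rnorm(length(Y), sd = sensor_spec$sensor_noise_sd),
                    nrow(Y), ncol(Y))
  tt <- (seq_len(n) - 1L) / sources$fs_hz
  if (sensor_spec$line_noise_amp > 0) {
    gains <- stats::runif(nrow(Y), 0.5, 1.5)
    Y <- Y + outer(gains, sensor_spec$line_noise_amp *
                     sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi)))
  }
  if (sensor_spec$dbs_amp > 0) {
    pulse <- as.numeric((tt * sensor_spec$dbs_rate_hz) %% 1 < sensor_spec$dbs_duty)
    pulse <- sensor_spec$dbs_amp * (pulse - mean(pulse))
    topo <- stats::rnorm(nrow(Y))
    topo <- topo / sqrt(sum(topo^2)) * sqrt(nrow(Y))
    Y <- Y + outer(topo, pulse)
  }
  rec <- mc_recording(Y, sources$fs_hz, labels = leadfield$sensor_labels,
                      space = "sensor")
  list(recording = rec, leadfield = leadfield)
}
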