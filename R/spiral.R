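#' Configuration of the synthetic spiral generator
#'
#' Describes how an Archimedean spiral r = spacing * theta / (2*pi) is traced
#' in time. The template geometry (1.5 cm loop spacing, three loops, 100 Hz
#' tablet sampling) mirrors a standard digitizer spiral task; the angular
#' speed grows with the stimulation level to emulate bradykinesia relief,
#' and a smooth random modulation of the angular speed (`entropy_knob`)
#' injects velocity irregularity that raises the sample entropy of the
#' tangential-velocity series.
#'
#' @param spacing_cm radial gain per loop of the spiral (cm).
#' @param n_loops number of full turns (>= 1).
#' @param fs_hz tablet sampling rate (Hz).
#' @param base_angular_speed angular speed at stimulation level 0 (rad/s).
#' @param level_speed_gain fractional angular-speed increase per stimulation
#'   level step (>= 0); the mean tangential velocity is then linear in level.
#' @param jitter_sd positional noise SD (cm) added to x and y.
#' @param tremor_amp,tremor_hz optional oscillatory contamination (cm, Hz);
#'   `tremor_amp = 0` disables it.
#' @param entropy_knob relative SD of the smooth angular-speed modulation
#'   (0 = perfectly regular drawing).
#' @param direction `"counterclockwise"` (left-handed template mirrored) or
#'   `"clockwise"`.
#' @return a validated `spiral_gen_config` list.
#' @export
spiral_gen_config <- function(spacing_cm = 1.5, n_loops = 3, fs_hz = 100,
                              base_angular_speed = 2 * pi * 3 / 14.3,
                              level_speed_gain = 0.12,
                              jitter_sd = 0, tremor_amp = 0, tremor_hz = 5,
                              entropy_knob = 0,
                              direction = c("counterclockwise", "clockwise")) {
  direction <- match.arg(direction)
  stopifnot(spacing_cm > 0, n_loops >= 1, fs_hz > 0,
            base_angular_speed > 0, level_speed_gain >= 0,
            jitter_sd >= 0, tremor_amp >= 0, tremor_hz > 0, entropy_knob >= 0)
  structure(list(
    spacing_cm = spacing_cm, n_loops = n_loops, fs_hz = fs_hz,
    base_angular_speed = base_angular_speed, level_speed_gain = level_speed_gain,
    jitter_sd = jitter_sd, tremor_amp = tremor_amp, tremor_hz = tremor_hz,
    entropy_knob = entropy_knob, direction = direction
  ), class = "spiral_gen_config")
}

#' Single drawn spiral
#'
#' @param t time stamps in seconds, strictly increasing.
#' @param x,y pen position in cm.
#' @param task `"self_paced"` or `"traced"`.
#' @param level stimulation level 0..3.
#' @param rep repeat index (1..5 in the standard protocol).
#' @param subject subject identifier.
#' @return a `spiral_trace` object.
#' @export
spiral_trace <- function(t, x, y, task = "self_paced", level = 0L,
                         rep = 1L, subject = "s01") {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) < 3L) stop("a spiral trace needs at least 3 samples")
  if (length(x) != length(t) || length(y) != length(t))
    stop("t, x, y must have equal length")
  if (anyNA(t) || anyNA(x) || anyNA(y)) stop("trace contains NaN/NA")
  if (any(diff(t) <= 0)) stop("time stamps must be strictly increasing")
  if (!task %in% c("self_paced", "traced")) stop("unknown task label")
  if (!level %in% 0:3) stop("stimulation level must be 0..3")
  structure(list(t = t, x = x, y = y, task = task,
                 level = as.integer(level), rep = as.integer(rep),
                 subject = subject),
            class = "spiral_trace")
}

#' @export
print.spiral_trace <- function(x, ...) {
  cat(sprintf("<spiral_trace> %s/%s level %d rep %d: %d samples over %.2f s\n",
              x$subject, x$task, x$level, x$rep, length(x$t), max(x$t) - min(x$t)))
  invisible(x)
}

# Smooth positive angular-speed modulation: exponentiated AR(1)-filtered noise
# so that theta stays strictly increasing whatever the knob.
.speed_modulation <- function(n, knob, fs) {
  if (knob == 0 || n == 0) return(rep(1, n))
  phi <- exp(-1 / (0.25 * fs))          # ~0.25 s correlation time
  z <- as.numeric(stats::filter(stats::rnorm(n), phi, method = "recursive"))
  z <- z * sqrt(1 - phi^2)              # unit marginal SD
  exp(knob * z - knob^2 / 2)            # mean ~1, relative SD ~knob
}

#' Generate one synthetic spiral at a stimulation level
#'
#' Traces the Archimedean spiral at angular speed
#' `base_angular_speed * (1 + level_speed_gain * level)`, modulated by the
#' entropy knob, until `n_loops` turns are complete. The analytic (noise-free)
#' tangential velocity of the generator is
#' `v_t(t) = spacing/(2*pi) * omega^2 * t`, stored in the returned trace's
#' `meta` field for ground-truth round trips.
#'
#' @param cfg a [spiral_gen_config()].
#' @param level stimulation level 0..3.
#' @param task,rep,subject metadata carried into the trace.
#' @param seed optional integer; when given the draw is reproducible.
#' @return a [spiral_trace()] with a `meta` list
#'   (`omega`, `spacing_cm`, `duration_s`).
#' @export
gen_spiral <- function(cfg, level, task = "self_paced", rep = 1L,
                       subject = "s01", seed = NULL) {
  stopifnot(inherits(cfg, "spiral_gen_config"), level %in% 0:3)
  if (!is.null(seed)) set.seed(seed)
  omega <- cfg$base_angular_speed * (1 + cfg$level_speed_gain * level)
  theta_end <- 2 * pi * cfg$n_loops
  dt <- 1 / cfg$fs_hz
  n_nom <- ceiling(theta_end / (omega * dt)) + 1L
  if (n_nom < 3L) stop("degenerate config: spiral would have < 3 samples")
  # draw enough modulation to certainly reach theta_end, then truncate
  n_max <- max(ceiling(1.5 * n_nom) + as.integer(10 * cfg$fs_hz), n_nom + 8L)
  mod <- .speed_modulation(n_max, cfg$entropy_knob, cfg$fs_hz)
  theta <- cumsum(c(0, omega * mod[-n_max] * dt))
  n <- which(theta >= theta_end)[1L]
  if (is.na(n)) n <- n_max
  theta <- theta[seq_len(n)]
  t <- (seq_len(n) - 1L) * dt
  r <- cfg$spacing_cm * theta / (2 * pi)
  sgn <- if (cfg$direction == "counterclockwise") 1 else -1
  x <- r * cos(theta)
  y <- sgn * r * sin(theta)
  if (cfg$tremor_amp > 0) {
    x <- x + cfg$tremor_amp * sin(2 * pi * cfg$tremor_hz * t)
    y <- y + cfg$tremor_amp * cos(2 * pi * cfg$tremor_hz * t)
  }
  if (cfg$jitter_sd > 0) {
    x <- x + stats::rnorm(n, sd = cfg$jitter_sd)
    y <- y + stats::rnorm(n, sd = cfg$jitter_sd)
  }
  tr <- spiral_trace(t, x, y, task = task, level = level, rep = rep,
                     subject = subject)
  tr$meta <- list(omega = omega, spacing_cm = cfg$spacing_cm,
                  duration_s = t[n])
  tr
}

#' Generate a cohort of spiral traces
#'
#' Produces the full within-subject design: 2 tasks x 4 stimulation levels x
#' `n_repeats` spirals per subject. Per-subject random effects are drawn once
#' per subject: a log-normal base-speed factor and a Gaussian speed gain per
#' level (truncated at 0). The traced task is drawn slightly slower and more
#' irregular than self-paced drawing, and switching stimulation on (levels
#' >= 1) shrinks the entropy knob by `entropy_on_drop` — irregularity reacts
#' to the ON state rather than to the graded intensity.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param cfg template [spiral_gen_config()].
#' @param effect list of cohort effect parameters:
#'   `gain_mean`, `gain_sd` (per-subject level speed gain distribution),
#'   `subject_speed_sd` (log-normal SD of base speed),
#'   `task_speed_factor` (traced vs self-paced speed ratio),
#'   `task_entropy_factor` (traced vs self-paced knob ratio),
#'   `entropy_on_drop` (fractional knob reduction when stimulation is on).
#' @param n_repeats spirals per condition (default 5).
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return list of [spiral_trace()] objects (subjects x tasks x levels x
#'   repeats), in deterministic order.
#' @export
gen_cohort_spirals <- function(n_subjects, cfg = spiral_gen_config(),
                               effect = list(), n_repeats = 5L, seed = 1L) {
  stopifnot(n_subjects >= 1)
  eff <- utils::modifyList(list(
    gain_mean = cfg$level_speed_gain, gain_sd = 0.04,
    subject_speed_sd = 0.15, task_speed_factor = 0.85,
    task_entropy_factor = 1.4, entropy_on_drop = 0.3
  ), effect)
  set.seed(seed)
  out <- vector("list", n_subjects * 2L * 4L * n_repeats)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%02d", s)
    speed_f <- exp(stats::rnorm(1, sd = eff$subject_speed_sd))
    gain_s <- max(0, stats::rnorm(1, eff$gain_mean, eff$gain_sd))
    for (task in c("self_paced", "traced")) {
      task_f <- if (task == "traced") eff$task_speed_factor else 1
      knob_f <- if (task == "traced") eff$task_entropy_factor else 1
      for (lev in 0:3) {
        knob_on <- if (lev >= 1) 1 - eff$entropy_on_drop else 1
        cfg_i <- cfg
        cfg_i$base_angular_speed <- cfg$base_angular_speed * speed_f * task_f
        cfg_i$level_speed_gain <- gain_s
        cfg_i$entropy_knob <- cfg$entropy_knob * knob_f * knob_on
        for (r in seq_len(n_repeats)) {
          k <- k + 1L
          out[[k]] <- gen_spiral(cfg_i, lev, task = task, rep = r, subject = sid)
        }
      }
    }
  }
  out
}
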