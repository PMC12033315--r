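#' Validated run configuration for the full pipeline
#'
#' Collects every tunable of the analysis chain with explicit defaults.
#' Unknown keys are rejected; every random step derives its seed from the
#' single `seed` entry, so a configuration fully determines the outputs.
#'
#' @param ... overrides of the default fields (see Details).
#' @details Fields: `seed`; `n_subjects`; `n_samples` (per condition source
#'   samples); `fs_hz` (neural simulation rate); `spiral` (list passed to
#'   [spiral_gen_config()]); `sensor` (list passed to [sensor_model_spec()]);
#'   `preprocess` (`hp_hz`, `lp_hz`, `order`, `notch`); `lcmv_lambda`;
#'   `mvar_order` (integer or `"auto"`); `cv` (`k_folds`, `n_repeats`);
#'   `sampen` (`m`, `r_frac`); `levels` (must be 0:3).
#' @return a `run_config` list with a `hash` attribute.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_subjects = 8L,
    n_samples = 3000L,
    fs_hz = 500,
    spiral = list(entropy_knob = 0.25, jitter_sd = 0.03),
    sensor = list(n_sensors = 64L, sensor_noise_sd = 0.3,
                  line_noise_amp = 0.5),
    preprocess = list(hp_hz = 0.5, lp_hz = 200, order = 4L,
                      notch = c(50, 100, 150)),
    lcmv_lambda = 0.05,
    mvar_order = 16L,
    cv = list(k_folds = 5L, n_repeats = 10L),
    sampen = list(m = 2L, r_frac = 0.2),
    levels = 0:3
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  stopifnot(identical(as.integer(cfg$levels), 0:3),
            cfg$n_subjects >= 1, cfg$n_samples > 0, cfg$fs_hz > 0,
            cfg$lcmv_lambda >= 0)
  if (cfg$preprocess$lp_hz >= cfg$fs_hz / 2)
    stop("preprocess$lp_hz must lie below the Nyquist frequency")
  cfg <- structure(cfg, class = "run_config")
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Deterministic short hash of a configuration
#'
#' Polynomial rolling hash over the deparsed configuration; embedded in
#' every output artifact so results can be traced to the exact settings
#' that produced them.
#'
#' @param cfg a `run_config` (or any R object).
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# per-condition EEG chain: simulate sources, mix to sensors, condition,
# beamform back to ROI series
.condition_sources <- function(model, cfg, leadfield, seed) {
  src <- simulate_mvar(model, cfg$n_samples, seed = seed)
  sens_spec <- do.call(sensor_model_spec, cfg$sensor)
  proj <- project_to_sensors(src, sens_spec, leadfield = leadfield,
                             seed = seed + 1L)
  rec <- preprocess_recording(proj$recording,
                              hp_hz = cfg$preprocess$hp_hz,
                              lp_hz = cfg$preprocess$lp_hz,
                              order = cfg$preprocess$order,
                              freqs = cfg$preprocess$notch)
  C <- estimate_covariance(rec, shrinkage = 0)
  filt <- lcmv_filters(proj$leadfield, C, lambda = cfg$lcmv_lambda)
  extract_sources(rec, filt)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages, in order: spiral generation and kinematics; per-condition neural
#' simulation, sensor projection, preprocessing, LCMV source extraction;
#' Welch band power and power slopes; MVAR/gPDC connectivity; group
#' statistics on the kinematic parameters; SVR + Shapley prediction of the
#' velocity slope from the measured power slopes (skipped with a message
#' when the cohort is smaller than the CV fold count). Every output table
#' carries the configuration hash; stage timings are logged.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional directory; when given, result TSV/JSON files are
#'   written there.
#' @param quiet suppress stage log messages.
#' @return list: `kinematics`, `velocity_slopes`, `power`, `power_slopes`,
#'   `connectivity`, `stats`, `prediction`, `config_hash`, `timings_s`.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- attr(cfg, "hash")
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- c()
  clock <- function(expr, stage) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    timings[stage] <<- unname(proc.time()[3] - t0)
    say("stage %-12s %6.1f s", stage, timings[stage])
    out
  }

  # --- kinematics ---------------------------------------------------------
  spiral_cfg <- do.call(spiral_gen_config, cfg$spiral)
  traces <- clock(gen_cohort_spirals(cfg$n_subjects, spiral_cfg,
                                     seed = cfg$seed), "spirals")
  kin <- clock({
    key <- vapply(traces, function(tr)
      paste(tr$subject, tr$task, tr$level, sep = "|"), character(1))
    do.call(rbind, lapply(split(traces, key), summarize_level,
                          m = cfg$sampen$m, r_frac = cfg$sampen$r_frac))
  }, "kinematics")
  rownames(kin) <- NULL
  vslopes <- do.call(rbind, lapply(
    split(kin, list(kin$subject, kin$task)), function(d) {
      d <- d[order(d$level), ]
      fit <- slope_across_levels(d$mean_velocity, d$level)
      data.frame(subject = d$subject[1], task = d$task[1],
                 velocity_slope = fit$slope, stringsAsFactors = FALSE)
    }))
  rownames(vslopes) <- NULL

  # --- neural chain per subject x task x level ----------------------------
  net <- default_network_spec(fs_hz = cfg$fs_hz, include_extra = TRUE)
  models <- lapply(cfg$levels, function(l) build_mvar_from_spec(net, l))
  names(models) <- as.character(cfg$levels)
  sens_spec <- do.call(sensor_model_spec, cfg$sensor)
  leadfield <- make_leadfield(sens_spec$n_sensors, length(net$roi_labels),
                              source_labels = net$roi_labels,
                              seed = sens_spec$leadfield_seed)
  motor <- c("M1", "SMA", "DPMC", "VPMC", "STN")
  pow_rows <- list(); con_rows <- list()
  clock({
    sub_i <- 0L
    for (s in unique(kin$subject)) {
      sub_i <- sub_i + 1L
      for (task in c("self_paced", "traced")) {
        recs <- lapply(cfg$levels, function(l) {
          seed_l <- (cfg$seed * 1000L + sub_i * 16L +
                       match(task, c("self_paced", "traced")) * 8L + l) %% 2147483647L
          .condition_sources(models[[as.character(l)]], cfg, leadfield, seed_l)
        })
        names(recs) <- as.character(cfg$levels)
        pw <- power_table(recs, subject = s, task = task)
        pow_rows[[length(pow_rows) + 1L]] <- pw
        con_rows[[length(con_rows) + 1L]] <-
          connectivity_table(recs, regions = motor, order = cfg$mvar_order,
                             subject = s, task = task)
      }
    }
  }, "neural")
  power <- do.call(rbind, lapply(pow_rows, `[[`, "power"))
  power_slopes <- do.call(rbind, lapply(pow_rows, `[[`, "slopes"))
  connectivity <- do.call(rbind, con_rows)

  # --- group statistics on kinematics -------------------------------------
  stats_out <- clock({
    res <- list()
    for (task in c("self_paced", "traced")) {
      d <- kin[kin$task == task, ]
      mat <- stats::xtabs(mean_velocity ~ subject + level, data = d)
      mat <- matrix(mat, nrow(mat), dimnames = dimnames(mat))
      if (nrow(mat) >= 2) {
        an <- rm_anova_level(mat)
        res[[paste0("anova_velocity_", task)]] <-
          data.frame(parameter = "mean_velocity", task = task, test = "rm_anova",
                     statistic = an$F, df1 = an$df1, df2 = an$df2, p = an$p)
      }
    }
    sp <- vslopes[vslopes$task == "self_paced", ]
    tr <- vslopes[vslopes$task == "traced", ]
    m <- merge(sp, tr, by = "subject", suffixes = c("_sp", "_tr"))
    if (nrow(m) >= 6) {
      pt <- paired_t(m$velocity_slope_sp, m$velocity_slope_tr)
      wx <- wilcoxon_signed_rank(m$velocity_slope_sp, m$velocity_slope_tr)
      res$slope_task_tests <- data.frame(
        parameter = "velocity_slope", task = "self_paced_vs_traced",
        test = c("paired_t", "wilcoxon"),
        statistic = c(pt$t, wx$W), df1 = c(pt$df, NA), df2 = NA,
        p = c(pt$p, wx$p))
    }
    do.call(rbind, res)
  }, "stats")

  # --- prediction ----------------------------------------------------------
  prediction <- clock({
    if (cfg$n_subjects < max(5L, cfg$cv$k_folds)) {
      say("prediction skipped: cohort too small for cross-validated SVR")
      NULL
    } else {
      out <- list()
      for (task in c("self_paced", "traced")) {
        yv <- vslopes[vslopes$task == task, ]
        for (b in band_definitions()$band) {
          ps <- power_slopes[power_slopes$band == b &
                               power_slopes$task == task, ]
          X <- stats::xtabs(slope ~ subject + roi, data = ps)
          X <- matrix(X, nrow(X), dimnames = dimnames(X))
          y <- yv$velocity_slope[match(rownames(X), yv$subject)]
          cv <- cv_r2(X, y, k_folds = cfg$cv$k_folds,
                      n_repeats = cfg$cv$n_repeats, seed = cfg$seed)
          model <- fit_svr_rbf(X, y)
          rk <- rank_features(exact_shapley(model, X))
          out[[paste(task, b, sep = ".")]] <-
            list(task = task, band = b, r2_mean = cv$r2_mean,
                 r2_sd = cv$r2_sd, ranking = rk)
        }
      }
      out
    }
  }, "predict")

  res <- list(kinematics = kin, velocity_slopes = vslopes, power = power,
              power_slopes = power_slopes, connectivity = connectivity,
              stats = stats_out, prediction = prediction,
              config_hash = hash, timings_s = timings)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(kin, file.path(out_dir, "kinematics.tsv"), hash)
    .write_tsv(vslopes, file.path(out_dir, "velocity_slopes.tsv"), hash)
    .write_tsv(power, file.path(out_dir, "band_power.tsv"), hash)
    .write_tsv(power_slopes, file.path(out_dir, "power_slopes.tsv"), hash)
    .write_tsv(connectivity, file.path(out_dir, "connectivity.tsv"), hash)
    if (!is.null(stats_out))
      .write_tsv(stats_out, file.path(out_dir, "stats.tsv"), hash)
    if (!is.null(prediction)) {
      summ <- do.call(rbind, lapply(prediction, function(p)
        data.frame(task = p$task, band = p$band, r2_mean = p$r2_mean,
                   r2_sd = p$r2_sd)))
      .write_tsv(summ, file.path(out_dir, "prediction_r2.tsv"), hash)
      jsonlite::write_json(
        list(config_hash = hash,
             prediction = lapply(prediction, function(p)
               list(task = p$task, band = p$band, r2_mean = p$r2_mean,
                    r2_sd = p$r2_sd,
                    top_features = utils::head(p$ranking$feature, 3)))),
        file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  res
}
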