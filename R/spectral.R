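#' The four analysis bands
#'
#' Low beta 13-20 Hz, high beta 21-30 Hz, low gamma 31-60 Hz and high gamma
#' 61-100 Hz (inclusive edges).
#'
#' @return data.frame with columns `band`, `lo`, `hi`.
#' @export
band_definitions <- function() {
  data.frame(band = c("low_beta", "high_beta", "low_gamma", "high_gamma"),
             lo = c(13, 21, 31, 61), hi = c(20, 30, 60, 100),
             stringsAsFactors = FALSE)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram over Hamming-windowed segments (default 1 s,
#' 50% overlap), one-sided density normalization so that the integral of the
#' PSD over 0..fs/2 equals the signal variance. Segments are demeaned before
#' windowing. Frequency resolution is `1/win_s` Hz.
#'
#' @param series numeric vector, at least one window long.
#' @param fs sampling rate (Hz).
#' @param win_s window length in seconds (default 1).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param demean subtract each segment's mean (default TRUE).
#' @return list with `freq` (Hz) and `psd` (power per Hz), class `welch_psd`.
#' @export
welch_psd <- function(series, fs, win_s = 1.0, overlap = 0.5, demean = TRUE) {
  series <- as.numeric(series)
  nwin <- round(win_s * fs)
  if (length(series) < nwin)
    stop("series shorter than one Welch window")
  stopifnot(overlap >= 0, overlap < 1)
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(series) - nwin + 1L, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))  # Hamming
  U <- sum(w^2)
  nf <- nwin %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- series[s0:(s0 + nwin - 1L)]
    if (demean) seg <- seg - mean(seg)
    ft <- stats::fft(seg * w)[1:nf]
    acc <- acc + (Mod(ft)^2) / (fs * U)
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nwin)
  dbl <- rep(2, nf); dbl[1L] <- 1
  if (nwin %% 2L == 0L) dbl[nf] <- 1
  psd <- psd * dbl
  structure(list(freq = (0:(nf - 1)) * fs / nwin, psd = psd,
                 fs = fs, win_s = win_s), class = "welch_psd")
}

#' Integrated band power from a PSD
#'
#' Trapezoidal integral of the one-sided density over `[lo, hi]` (both
#' endpoints included on the frequency grid).
#'
#' @param psd a [welch_psd()] result (or list with `freq`, `psd`).
#' @param lo,hi band edges in Hz; or pass `band` as a row of
#'   [band_definitions()].
#' @param band optional one-row data.frame with `lo` and `hi`.
#' @return integrated power (signal units squared).
#' @export
band_power <- function(psd, lo = NULL, hi = NULL, band = NULL) {
  if (!is.null(band)) { lo <- band$lo; hi <- band$hi }
  stopifnot(!is.null(lo), !is.null(hi), hi > lo)
  if (hi > max(psd$freq))
    stop("band exceeds the Nyquist range of the PSD")
  sel <- which(psd$freq >= lo & psd$freq <= hi)
  if (length(sel) < 2L) stop("band contains fewer than 2 grid points")
  f <- psd$freq[sel]; d <- psd$psd[sel]
  sum(diff(f) * (d[-1] + d[-length(d)]) / 2)
}

#' Band power table across stimulation levels, with slopes
#'
#' Computes Welch band power for every ROI channel of each per-level source
#' recording and each analysis band, then fits the least-squares slope of
#' power on the ordinal level index per (ROI, band).
#'
#' @param recs_by_level named list of source-space [mc_recording()]s, one per
#'   stimulation level; names are the level indices ("0".."3"). Missing
#'   levels are allowed (slope fitted on the available ones, flagged).
#' @param bands band table as from [band_definitions()].
#' @param subject,task metadata columns carried into the table.
#' @param win_s Welch window length (s).
#' @return list with `power` (long data.frame: subject, task, roi, band,
#'   level, power) and `slopes` (subject, task, roi, band, slope, n_levels).
#' @export
power_table <- function(recs_by_level, bands = band_definitions(),
                        subject = "s01", task = "self_paced", win_s = 1.0) {
  stopifnot(length(recs_by_level) >= 1)
  if (is.null(names(recs_by_level)))
    names(recs_by_level) <- as.character(seq_along(recs_by_level) - 1L)
  rows <- list()
  for (lev in names(recs_by_level)) {
    rec <- recs_by_level[[lev]]
    stopifnot(inherits(rec, "mc_recording"))
    for (ch in seq_len(nrow(rec$data))) {
      psd <- welch_psd(rec$data[ch, ], rec$fs_hz, win_s = win_s)
      for (b in seq_len(nrow(bands))) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subject, task = task, roi = rec$labels[ch],
          band = bands$band[b], level = as.integer(lev),
          power = band_power(psd, bands$lo[b], bands$hi[b]),
          stringsAsFactors = FALSE)
      }
    }
  }
  pow <- do.call(rbind, rows)
  sl <- lapply(split(pow, list(pow$roi, pow$band), drop = TRUE), function(d) {
    fit <- slope_across_levels(d$power, d$level)
    data.frame(subject = subject, task = task, roi = d$roi[1], band = d$band[1],
               slope = fit$slope, n_levels = length(fit$levels),
               stringsAsFactors = FALSE)
  })
  slopes <- do.call(rbind, sl)
  rownames(slopes) <- NULL
  if (any(slopes$n_levels < 4L))
    warning("slope fitted on fewer than 4 levels for some ROI/band entries")
  list(power = pow, slopes = slopes)
}
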