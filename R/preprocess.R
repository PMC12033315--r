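#' Common average reference
#'
#' Subtracts the instantaneous mean over all channels from every channel, so
#' each sample's column sum is zero to numerical tolerance.
#'
#' @param rec an [mc_recording()] with >= 2 channels.
#' @return the re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "mc_recording"))
  if (nrow(rec$data) < 2L)
    stop("common average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec
}

# zero-phase (forward-backward) application of an IIR filter to each channel
.filtfilt_rows <- function(data, filt) {
  t(apply(data, 1L, function(ch) signal::filtfilt(filt, ch)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth high-pass and low-pass applied forward-backward
#' (`signal::filtfilt`), which cancels the phase response — protecting the
#' cross-region phase relations that directed-coherence estimates depend
#' on — at the price of doubling the effective order.
#'
#' @param rec an [mc_recording()].
#' @param hp_hz high-pass edge (Hz); `0` disables.
#' @param lp_hz low-pass edge (Hz), must be below Nyquist; `Inf` disables.
#' @param order filter order per pass (default 4).
#' @return the filtered recording.
#' @export
butterworth_filter <- function(rec, hp_hz = 0.5, lp_hz = 300, order = 4L) {
  stopifnot(inherits(rec, "mc_recording"))
  nyq <- rec$fs_hz / 2
  if (is.finite(lp_hz) && lp_hz >= nyq)
    stop("low-pass edge must lie below the Nyquist frequency")
  if (hp_hz > 0) {
    bh <- signal::butter(order, hp_hz / nyq, type = "high")
    rec$data <- .filtfilt_rows(rec$data, bh)
  }
  if (is.finite(lp_hz)) {
    bl <- signal::butter(order, lp_hz / nyq, type = "low")
    rec$data <- .filtfilt_rows(rec$data, bl)
  }
  rec
}

#' Zero-phase notch filters for line noise and harmonics
#'
#' Second-order IIR notches (quality factor `q`, i.e. -3 dB width f0/q)
#' at each requested frequency, applied forward-backward.
#'
#' @param rec an [mc_recording()].
#' @param freqs notch frequencies in Hz (default 50/100/150, line noise and
#'   harmonics), all below Nyquist.
#' @param q quality factor of each notch (default 35).
#' @return the filtered recording.
#' @export
notch_filter <- function(rec, freqs = c(50, 100, 150), q = 35) {
  stopifnot(inherits(rec, "mc_recording"))
  nyq <- rec$fs_hz / 2
  if (any(freqs >= nyq)) stop("notch frequencies must lie below Nyquist")
  for (f0 in freqs) {
    w0 <- 2 * pi * f0 / rec$fs_hz
    alpha <- sin(w0) / (2 * q)
    b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
    a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
    flt <- signal::Arma(b = b, a = a)
    rec$data <- .filtfilt_rows(rec$data, flt)
  }
  rec
}

#' Standard sensor-space conditioning chain
#'
#' Applies, in order: common average reference, band-pass Butterworth,
#' notch filters. The order is fixed by the driver.
#'
#' @param rec an [mc_recording()].
#' @inheritParams butterworth_filter
#' @inheritParams notch_filter
#' @return the conditioned recording.
#' @export
preprocess_recording <- function(rec, hp_hz = 0.5, lp_hz = 300, order = 4L,
                                 freqs = c(50, 100, 150), q = 35) {
  rec <- common_average_reference(rec)
  rec <- butterworth_filter(rec, hp_hz = hp_hz, lp_hz = lp_hz, order = order)
  notch_filter(rec, freqs = freqs, q = q)
}
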