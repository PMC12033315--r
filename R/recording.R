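#' Multichannel recording container
#'
#' Bundles a channels-by-samples numeric matrix with its sampling rate,
#' channel labels and the space it lives in (sensor or source). All
#' downstream stages (filtering, beamforming, spectral and connectivity
#' analysis) consume and return this container.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param labels character vector of unique channel labels; defaults to
#'   `ch1..chK`.
#' @param space `"sensor"` or `"source"`.
#' @return An object of class `mc_recording` with elements `data`, `fs_hz`,
#'   `labels`, `space`.
#' @export
mc_recording <- function(data, fs_hz, labels = NULL, space = c("sensor", "source")) {
  space <- match.arg(space)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  if (anyNA(data)) stop("recording data contains NaN/NA")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("fs_hz must be a single positive number")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) stop("one label per channel required")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  structure(
    list(data = data, fs_hz = fs_hz, labels = labels, space = space),
    class = "mc_recording"
  )
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf(
    "<mc_recording> %d channels x %d samples @ %g Hz (%s space)\n",
    nrow(x$data), ncol(x$data), x$fs_hz, x$space
  ))
  invisible(x)
}

#' @export
dim.mc_recording <- function(x) dim(x$data)

#' Number of channels / samples of a recording
#' @param rec an [mc_recording()].
#' @return integer count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Concatenate epochs recorded under one condition
#'
#' Joins several recordings of the same montage along the sample dimension,
#' e.g. the five drawing epochs acquired at one stimulation level, so that
#' spectra and connectivity are estimated from the pooled data.
#'
#' @param recs list of [mc_recording()] objects with identical sampling rate,
#'   labels and space.
#' @return a single [mc_recording()]; sample count is the sum of the inputs'.
#' @export
concatenate_epochs <- function(recs) {
  if (!length(recs)) stop("no epochs to concatenate")
  if (!all(vapply(recs, inherits, logical(1), "mc_recording")))
    stop("all epochs must be mc_recording objects")
  ref <- recs[[1L]]
  for (r in recs[-1L]) {
    if (!isTRUE(all.equal(r$fs_hz, ref$fs_hz))) stop("sampling rates differ between epochs")
    if (!identical(r$labels, ref$labels)) stop("channel labels differ between epochs")
    if (!identical(r$space, ref$space)) stop("epochs live in different spaces")
  }
  mc_recording(do.call(cbind, lapply(recs, `[[`, "data")),
               ref$fs_hz, ref$labels, ref$space)
}
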