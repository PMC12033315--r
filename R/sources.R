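#' Sensor covariance with optional diagonal loading
#'
#' Sample covariance of the channels (rows), with shrinkage
#' `C + lambda * mean(diag(C)) * I` when `shrinkage > 0`. Shrinkage is
#' mandatory when there are fewer samples than sensors.
#'
#' @param rec an [mc_recording()].
#' @param shrinkage loading factor lambda (>= 0).
#' @return symmetric positive semi-definite covariance matrix.
#' @export
estimate_covariance <- function(rec, shrinkage = 0) {
  stopifnot(inherits(rec, "mc_recording"), shrinkage >= 0)
  v <- apply(rec$data, 1L, stats::var)
  if (any(v == 0))
    stop("constant channels: ", paste(rec$labels[v == 0], collapse = ", "))
  if (ncol(rec$data) < nrow(rec$data) && shrinkage == 0)
    stop("fewer samples than sensors: diagonal loading is mandatory")
  X <- rec$data - rowMeans(rec$data)
  C <- tcrossprod(X) / (ncol(X) - 1L)
  C <- (C + t(C)) / 2
  if (shrinkage > 0) C <- C + shrinkage * mean(diag(C)) * diag(nrow(C))
  dimnames(C) <- list(rec$labels, rec$labels)
  C
}

#' LCMV beamformer spatial filters
#'
#' For each source s with lead-field column l_s, the linearly constrained
#' minimum-variance filter is
#' `w_s = (l_s' C^-1 l_s)^-1 l_s' C^-1`:
#' it passes activity from the source location with unit gain
#' (`w_s' l_s = 1`) while minimizing the output variance `w_s' C w_s`,
#' thereby suppressing contributions from all other locations.
#'
#' @param leadfield a `lead_field` (see [make_leadfield()] or
#'   [read_leadfield_tsv()]).
#' @param C sensor covariance (positive definite after loading).
#' @param lambda diagonal loading applied to `C` before inversion, as a
#'   fraction of its mean diagonal (default 0.05).
#' @param max_cond condition-number threshold beyond which an error asks for
#'   more loading.
#' @return a `spatial_filter_set`: `weights` (sources x sensors),
#'   `source_labels`, `sensor_labels`, `lambda`, `condition_number`.
#' @export
lcmv_filters <- function(leadfield, C, lambda = 0.05, max_cond = 1e10) {
  stopifnot(inherits(leadfield, "lead_field"))
  L <- leadfield$matrix
  C <- as.matrix(C)
  stopifnot(nrow(C) == nrow(L), ncol(C) == nrow(L))
  Cl <- C + lambda * mean(diag(C)) * diag(nrow(C))
  ev <- eigen(Cl, symmetric = TRUE, only.values = TRUE)$values
  cond <- max(ev) / max(min(ev), .Machine$double.xmin)
  if (min(ev) <= 0 || cond > max_cond)
    stop(sprintf(
      "covariance ill-conditioned (condition number %.3g): increase lambda",
      cond))
  CiL <- solve(Cl, L)                       # C^-1 L, sensors x sources
  gains <- colSums(L * CiL)                 # l_s' C^-1 l_s
  W <- t(CiL) / gains                       # rows w_s
  structure(list(weights = W, source_labels = leadfield$source_labels,
                 sensor_labels = leadfield$sensor_labels,
                 lambda = lambda, condition_number = cond),
            class = "spatial_filter_set")
}

#' @export
print.spatial_filter_set <- function(x, ...) {
  cat(sprintf("<spatial_filter_set> %d sources x %d sensors (lambda=%g, cond=%.3g)\n",
              nrow(x$weights), ncol(x$weights), x$lambda, x$condition_number))
  invisible(x)
}

#' Extract ROI source time series with beamformer filters
#'
#' source data = W * sensor data; channel labels become the ROI names.
#'
#' @param rec sensor-space [mc_recording()] whose labels match the filters'.
#' @param filters a `spatial_filter_set` from [lcmv_filters()].
#' @return an [mc_recording()] in source space.
#' @export
extract_sources <- function(rec, filters) {
  stopifnot(inherits(rec, "mc_recording"),
            inherits(filters, "spatial_filter_set"))
  if (!identical(rec$labels, filters$sensor_labels))
    stop("sensor labels of recording and filters do not match")
  mc_recording(filters$weights %*% rec$data, rec$fs_hz,
               labels = filters$source_labels, space = "source")
}
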