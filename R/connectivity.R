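#' Fit a multivariate autoregressive model by least squares
#'
#' Multichannel ordinary least squares on lagged regressors (equivalent to
#' the multivariate Yule-Walker solution for large n); the innovation
#' covariance is estimated from the residuals with a degrees-of-freedom
#' correction. With `order = "auto"`, the order minimizing the multivariate
#' BIC `log det(Sigma_ML) + log(N)/N * p * K^2` over `1..p_max` is chosen.
#'
#' @param sources a source-space [mc_recording()] (or any channels x samples
#'   recording).
#' @param order integer model order >= 1, or `"auto"`.
#' @param p_max maximal order scanned when `order = "auto"` (default 20).
#' @return an [mvar_model()] with attributes `bic` (when auto) and
#'   `stable_fit` (FALSE triggers a warning, not an error).
#' @export
fit_mvar <- function(sources, order = "auto", p_max = 20L) {
  stopifnot(inherits(sources, "mc_recording"))
  X <- sources$data
  K <- nrow(X); n <- ncol(X)
  if (identical(order, "auto")) {
    bics <- vapply(seq_len(p_max), function(p) .mvar_bic(X, p), numeric(1))
    order <- which.min(bics)
  } else {
    order <- as.integer(order)
    if (order < 1L) stop("order must be >= 1")
    bics <- NULL
  }
  p <- order
  if (n <= 10 * p * K)
    warning("short series for the requested order: n <= 10 * p * K")
  fit <- .mvar_ols(X, p)
  model <- mvar_model(fit$A, fit$Sigma, sources$fs_hz, sources$labels)
  if (!mvar_is_stable(model)) {
    warning("fitted MVAR model is not stable")
    attr(model, "stable_fit") <- FALSE
  } else attr(model, "stable_fit") <- TRUE
  if (!is.null(bics)) attr(model, "bic") <- bics
  model
}

# least-squares MVAR fit at fixed order
.mvar_ols <- function(X, p) {
  K <- nrow(X); n <- ncol(X)
  if (n <= p + 1L) stop("series too short for the requested order")
  Y <- t(X[, (p + 1):n, drop = FALSE])                  # (n-p) x K
  Z <- matrix(0, n - p, K * p)
  for (r in seq_len(p))
    Z[, ((r - 1) * K + 1):(r * K)] <- t(X[, (p + 1 - r):(n - r), drop = FALSE])
  ZtZ <- crossprod(Z)
  qrz <- qr(ZtZ)
  if (qrz$rank < ncol(Z)) stop("singular regressor matrix in MVAR fit")
  B <- solve(qrz, crossprod(Z, Y))                      # (K*p) x K
  resid <- Y - Z %*% B
  df <- max(1L, n - p - K * p)
  Sigma <- crossprod(resid) / df
  A <- array(0, dim = c(K, K, p))
  for (r in seq_len(p))
    A[, , r] <- t(B[((r - 1) * K + 1):(r * K), , drop = FALSE])
  list(A = A, Sigma = (Sigma + t(Sigma)) / 2,
       Sigma_ml = crossprod(resid) / (n - p))
}

.mvar_bic <- function(X, p) {
  K <- nrow(X); n <- ncol(X)
  fit <- .mvar_ols(X, p)
  Neff <- n - p
  d <- determinant(fit$Sigma_ml, logarithm = TRUE)
  as.numeric(d$modulus) + log(Neff) / Neff * p * K^2
}

#' Frequency-domain MVAR coefficient matrix
#'
#' Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs), evaluated on a frequency
#' grid. This is the matrix whose entries enter the generalized partial
#' directed coherence.
#'
#' @param model an [mvar_model()].
#' @param freqs frequencies in Hz, within `[0, fs/2]`.
#' @return complex array K x K x length(freqs).
#' @export
spectral_transfer <- function(model, freqs) {
  stopifnot(inherits(model, "mvar_model"),
            all(freqs >= 0), all(freqs <= model$fs_hz / 2))
  K <- model$K; p <- model$p; nf <- length(freqs)
  Aflat <- matrix(model$A, K * K, p)                    # (K^2) x p
  phase <- exp(-2i * pi * outer(seq_len(p), freqs) / model$fs_hz)  # p x nf
  S <- Aflat %*% phase                                  # (K^2) x nf
  out <- array(-S, dim = c(K, K, nf))
  for (f in seq_len(nf)) out[, , f] <- out[, , f] + diag(K)
  out
}

#' Generalized partial directed coherence
#'
#' `|pi_ij(f)| = (1/sigma_i) |Abar_ij(f)| /
#'   sqrt( sum_k (1/sigma_k^2) |Abar_kj(f)|^2 )`,
#' where sigma_k is the innovation SD of region k. The measure is the ratio
#' of the outflow from region j to region i relative to all outflows from
#' region j at frequency f; by construction the squared entries of each
#' column sum to one and every entry lies in [0, 1].
#'
#' @param model an [mvar_model()] with strictly positive innovation
#'   variances.
#' @param freqs frequency grid in Hz (default 1-100 Hz at 0.5 Hz spacing,
#'   clipped to Nyquist).
#' @return a `gpdc_spectrum`: `freqs`, `pi_abs` (K x K x F, `[i, j, f]` =
#'   coupling j -> i), `Abar`, `labels`.
#' @export
gpdc <- function(model, freqs = NULL) {
  stopifnot(inherits(model, "mvar_model"))
  sig2 <- diag(model$Sigma)
  if (any(sig2 <= 0)) stop("zero innovation variance: gPDC undefined")
  if (is.null(freqs))
    freqs <- seq(1, min(100, model$fs_hz / 2), by = 0.5)
  Abar <- spectral_transfer(model, freqs)
  K <- model$K; nf <- length(freqs)
  wa <- Mod(Abar) / sqrt(sig2)            # (1/sigma_i)|Abar_ij|, recycled by row
  denom <- sqrt(apply(wa^2, c(2, 3), sum))   # column normalizer per (j, f)
  pi_abs <- array(0, dim = c(K, K, nf))
  for (f in seq_len(nf))
    pi_abs[, , f] <- wa[, , f] / rep(denom[, f], each = K)
  structure(list(freqs = freqs, pi_abs = pi_abs, Abar = Abar,
                 labels = model$labels), class = "gpdc_spectrum")
}

#' @export
print.gpdc_spectrum <- function(x, ...) {
  cat(sprintf("<gpdc_spectrum> %d regions, %d frequencies (%.3g-%.3g Hz)\n",
              dim(x$pi_abs)[1], length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Band-mean gPDC for ordered region pairs
#'
#' Arithmetic mean of `|pi_ij(f)|` over the grid points inside `[lo, hi]`,
#' for every ordered (source, target) pair of the requested regions.
#'
#' @param spec a `gpdc_spectrum` from [gpdc()].
#' @param lo,hi band edges (Hz); or `band` as a row of [band_definitions()].
#' @param band optional one-row data.frame with `lo`, `hi` (and `band` name).
#' @param regions region labels to restrict to (default: all).
#' @return data.frame with columns `src`, `dst`, `band`, `gpdc` (self-pairs
#'   excluded).
#' @export
band_mean_gpdc <- function(spec, lo = NULL, hi = NULL, band = NULL,
                           regions = NULL) {
  stopifnot(inherits(spec, "gpdc_spectrum"))
  bname <- NA_character_
  if (!is.null(band)) { lo <- band$lo; hi <- band$hi; bname <- band$band }
  stopifnot(!is.null(lo), !is.null(hi))
  sel <- which(spec$freqs >= lo & spec$freqs <= hi)
  if (!length(sel)) stop("no frequency grid points inside the band")
  if (is.null(regions)) regions <- spec$labels
  idx <- match(regions, spec$labels)
  if (anyNA(idx)) stop("unknown region label(s)")
  bm <- apply(spec$pi_abs[, , sel, drop = FALSE], c(1, 2), mean)
  out <- expand.grid(dst = regions, src = regions, stringsAsFactors = FALSE)
  out <- out[out$src != out$dst, c("src", "dst")]
  out$band <- bname
  out$gpdc <- bm[cbind(idx[match(out$dst, regions)],
                       idx[match(out$src, regions)])]
  rownames(out) <- NULL
  out
}

#' Model power spectral density of an MVAR process
#'
#' S(f) = H(f) Sigma H(f)^* / fs with H = Abar^-1, one-sided (doubled for
#' f > 0). Returns the auto-spectra.
#'
#' @param model an [mvar_model()].
#' @param freqs frequencies in Hz.
#' @return matrix K x length(freqs) of one-sided PSD values.
#' @export
mvar_spectrum <- function(model, freqs) {
  Abar <- spectral_transfer(model, freqs)
  K <- model$K
  out <- matrix(0, K, length(freqs))
  for (f in seq_along(freqs)) {
    H <- solve(Abar[, , f])
    S <- H %*% model$Sigma %*% Conj(t(H)) / model$fs_hz
    out[, f] <- Re(diag(S)) * ifelse(freqs[f] > 0, 2, 1)
  }
  rownames(out) <- model$labels
  out
}

#' Phase-randomized surrogate of a recording
#'
#' Randomizes the Fourier phases of each channel independently while keeping
#' the amplitude spectra, which destroys cross-channel (directed) coupling
#' but preserves each channel's autocorrelation. Used to build a null
#' distribution for band-mean gPDC.
#'
#' @param rec an [mc_recording()].
#' @param seed optional RNG seed.
#' @return surrogate [mc_recording()].
#' @export
phase_randomize <- function(rec, seed = NULL) {
  stopifnot(inherits(rec, "mc_recording"))
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(rec$data)
  half <- (n - 1) %/% 2
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    ft <- stats::fft(rec$data[ch, ])
    ph <- stats::runif(half, 0, 2 * pi)
    rot <- rep(1 + 0i, n)
    rot[2:(half + 1)] <- exp(1i * ph)
    rot[n:(n - half + 1)] <- Conj(rot[2:(half + 1)])
    out$data[ch, ] <- Re(stats::fft(ft * rot, inverse = TRUE) / n)
  }
  out
}

#' Connectivity table across stimulation levels
#'
#' Fits one MVAR model per stimulation level on the (concatenated) source
#' recording of that level and tabulates band-mean gPDC for the analyzed
#' region set.
#'
#' @param recs_by_level named list of source recordings, one per level.
#' @param bands band table (default [band_definitions()]).
#' @param regions region set (default the five motor regions present in the
#'   recordings' labels).
#' @param order MVAR order policy passed to [fit_mvar()].
#' @param subject,task metadata columns.
#' @return long data.frame: subject, task, band, src, dst, level, gpdc.
#' @export
connectivity_table <- function(recs_by_level, bands = band_definitions(),
                               regions = NULL, order = "auto",
                               subject = "s01", task = "self_paced") {
  if (is.null(names(recs_by_level)))
    names(recs_by_level) <- as.character(seq_along(recs_by_level) - 1L)
  rows <- list()
  for (lev in names(recs_by_level)) {
    rec <- recs_by_level[[lev]]
    if (is.null(regions)) regions <- rec$labels
    sub <- mc_recording(rec$data[match(regions, rec$labels), , drop = FALSE],
                        rec$fs_hz, labels = regions, space = "source")
    model <- fit_mvar(sub, order = order)
    gp <- gpdc(model)
    for (b in seq_len(nrow(bands))) {
      tab <- band_mean_gpdc(gp, band = bands[b, ], regions = regions)
      tab$subject <- subject; tab$task <- task
      tab$level <- as.integer(lev)
      rows[[length(rows) + 1L]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  out[, c("subject", "task", "band", "src", "dst", "level", "gpdc")]
}
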