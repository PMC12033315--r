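#' Paired t-test on matched observations
#'
#' Classical paired t on the differences, two-sided.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return list `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1L, p = 1,
                                 mean_diff = 0, flag = "zero_variance"))
    stop("zero-variance non-zero differences")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), flag = NA_character_)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Statistic W+ (sum of ranks of positive differences). Zero differences are
#' dropped (Wilcoxon's original prescription). For n <= `exact_max` pairs
#' without ties, the exact two-sided p is computed from the signed-rank null
#' distribution; otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y numeric vectors of equal length.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return list `W` (W+), `n` (non-zero pairs), `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  nz <- d != 0
  if (!any(nz)) stop("all differences are zero: test undefined")
  d <- d[nz]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    # exact two-sided p from the signed-rank null (equivalent to 2^n
    # enumeration of sign assignments)
    p_lo <- stats::psignrank(W, n)
    p_hi <- 1 - stats::psignrank(W - 1, n)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(W = W, n = n, p = p, method = method)
}

# sums of squares for the one-within-factor design; used for the Tukey
# error term (identical to the aov "Within" stratum on complete data)
.rm_ss <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_level <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_level - ss_subj
  list(ss_level = ss_level, ss_err = ss_err,
       df1 = k - 1, df2 = (k - 1) * (n - 1))
}

#' One-within-factor repeated-measures ANOVA across stimulation levels
#'
#' Subjects x levels table; the level effect is tested against the
#' subject-by-level interaction mean square: F(k-1, (k-1)(n-1)). Rows with
#' missing cells are dropped listwise with a warning. An optional
#' Greenhouse-Geisser correction adjusts the degrees of freedom for
#' sphericity violations.
#'
#' @param mat numeric matrix, subjects (rows) x levels (columns, labelled
#'   0..k-1).
#' @param gg apply the Greenhouse-Geisser epsilon correction (default FALSE).
#' @return list `F`, `df1`, `df2`, `p`, `ms_err`, `n`, and `epsilon` when
#'   `gg = TRUE`.
#' @export
rm_anova_level <- function(mat, gg = FALSE) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    keep <- stats::complete.cases(mat)
    warning(sprintf("dropping %d subject(s) with missing cells", sum(!keep)))
    mat <- mat[keep, , drop = FALSE]
  }
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need at least 2 subjects and 2 levels")
  dat <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(nrow(mat)), ncol(mat))),
    level = factor(rep(seq_len(ncol(mat)) - 1L, each = nrow(mat))))
  fit <- stats::aov(y ~ level + Error(subject), data = dat)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  ss_level <- tab["level", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  df1 <- tab["level", "Df"]; df2 <- tab["Residuals", "Df"]
  ms_level <- ss_level / df1
  ms_err <- ss_err / df2
  # guard against rounding noise when the level means are numerically equal
  ss_tot <- sum((mat - mean(mat))^2)
  Fv <- if (ss_level <= 1e-12 * max(ss_tot, .Machine$double.xmin)) 0
        else if (ms_err == 0) Inf
        else ms_level / ms_err
  eps <- NULL
  if (gg) {
    S <- stats::cov(mat)
    k <- ncol(mat)
    num <- (k * mean(diag(S)) - mean(S))^2
    den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mean(S)^2)
    eps <- max(1 / (k - 1), min(1, num / den))
    df1 <- df1 * eps; df2 <- df2 * eps
  }
  p <- if (Fv == 0) 1 else stats::pf(Fv, df1, df2, lower.tail = FALSE)
  out <- list(F = Fv, df1 = df1, df2 = df2, p = p,
              ms_err = ms_err, n = nrow(mat))
  if (gg) out$epsilon <- eps
  out
}

#' Tukey HSD post hoc comparisons across stimulation levels
#'
#' Studentized-range statistics on the level means, with the
#' subject-by-level interaction mean square as the error term (the
#' repeated-measures analogue of the classical Tukey test):
#' `q = |mean_a - mean_b| / sqrt(MS_err / n)`, p from `ptukey` with
#' `k` means and the interaction degrees of freedom.
#'
#' @param mat subjects x levels matrix (complete cases used, as in
#'   [rm_anova_level()]).
#' @return data.frame: `level_a`, `level_b`, `diff`, `q`, `p_adj` for all
#'   level pairs.
#' @export
tukey_hsd <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 levels")
  ss <- .rm_ss(mat)
  ms_err <- ss$ss_err / ss$df2
  mns <- colMeans(mat)
  levs <- colnames(mat)
  if (is.null(levs)) levs <- as.character(seq_len(k) - 1L)
  pairs <- utils::combn(k, 2)
  se <- sqrt(ms_err / n)
  out <- data.frame(
    level_a = levs[pairs[1, ]], level_b = levs[pairs[2, ]],
    diff = mns[pairs[2, ]] - mns[pairs[1, ]],
    stringsAsFactors = FALSE)
  out$q <- abs(out$diff) / se
  out$p_adj <- stats::ptukey(out$q, nmeans = k, df = ss$df2,
                             lower.tail = FALSE)
  rownames(out) <- NULL
  out
}
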