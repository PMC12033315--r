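# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by the most literal method available (nested loops,
# exhaustive enumeration, hand-partitioned sums of squares) so they share no
# code with the implementation they check.

# O(N^2) nested-loop sample entropy (Richman-Moorman counts)
sampen_bruteforce <- function(x, m = 2L, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * sd(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) B <- B + 1L
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1L
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
wilcoxon_enumerate <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W_obs <- sum(rk[d > 0])
  Ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0
    sum(rk[signs])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  # two-sided: double the smaller tail
  p_lo <- mean(Ws <= W_obs)
  p_hi <- mean(Ws >= W_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# hand-partitioned sums of squares for the one-within-factor RM-ANOVA
rm_anova_bysums <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_level <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_err <- sum((mat - grand)^2) - ss_level - ss_subj
  Fv <- (ss_level / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(F = Fv, df1 = k - 1, df2 = (k - 1) * (n - 1),
       p = pf(Fv, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
}

# direct elementwise evaluation of the gPDC formula for one (i, j, f)
gpdc_by_hand <- function(A, Sigma, fs, i, j, f) {
  K <- dim(A)[1]; p <- dim(A)[3]
  Abar <- diag(K) + 0i
  for (r in 1:p) Abar <- Abar - A[, , r] * exp(-2i * pi * f * r / fs)
  sig <- sqrt(diag(Sigma))
  num <- Mod(Abar[i, j]) / sig[i]
  den <- sqrt(sum(Mod(Abar[, j])^2 / sig^2))
  num / den
}

# amplitude of a sinusoid channel measured away from filter edge transients
interior_amplitude <- function(x, fs, skip_s = 2) {
  mid <- x[(skip_s * fs):(length(x) - skip_s * fs)]
  sqrt(2 * mean(mid^2))
}

# small stable random MVAR model for recovery experiments
random_stable_mvar <- function(K, p, fs = 500, seed = 1, sd = 0.12,
                               diag_boost = 0.4) {
  set.seed(seed)
  repeat {
    A <- array(rnorm(K * K * p, sd = sd), c(K, K, p))
    for (i in 1:K) A[i, i, 1] <- A[i, i, 1] + diag_boost
    m <- mvar_model(A, diag(K), fs)
    if (mvar_is_stable(m, tol = 0.05)) return(m)
  }
}
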