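test_that("SVR handles constant targets and zero-variance features", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  out <- cv_r2(X, rep(2, 10), seed = 1)
  expect_equal(out$r2_mean, 0)
  expect_equal(out$flag, "constant_response")
  X2 <- cbind(X, e = rep(1, 10))
  expect_warning(m <- fit_svr_rbf(X2, rnorm(10)), "zero-variance")
  expect_false("e" %in% m$features)
  expect_error(fit_svr_rbf(X[1:3, ], rnorm(3)), "at least 5")
})

test_that("SVR interpolates an RBF-representable function when unconstrained", {
  set.seed(2)
  X <- matrix(rnorm(16 * 3), 16, 3, dimnames = list(NULL, c("a", "b", "c")))
  Xs <- scale(X)
  Kmat <- exp(-as.matrix(dist(Xs))^2 / 3)
  y <- drop(Kmat %*% rnorm(16, sd = 0.5))
  m <- fit_svr_rbf(X, y, cost = 1e4, epsilon = 0, gamma = 1 / 3)
  expect_lt(max(abs(predict(m, X) - y)), 1e-3)
})

test_that("SVR predictions are invariant to feature-column order", {
  co <- gen_cohort_features(seed = 3)
  m1 <- fit_svr_rbf(co$X, co$y)
  perm <- sample(ncol(co$X))
  m2 <- fit_svr_rbf(co$X[, perm], co$y)
  expect_equal(predict(m1, co$X), predict(m2, co$X[, perm]), tolerance = 1e-9)
})

test_that("cross-validated R2 is near 1 for perfect signal and reproducible", {
  set.seed(4)
  X <- matrix(rnorm(38), 38, 1, dimnames = list(NULL, "a"))
  y <- X[, 1]
  # interpolation regime: no tube, loose cost bound
  out <- cv_r2(X, y, seed = 7, cost = 1000, epsilon = 0)
  expect_gt(out$r2_mean, 0.99)
  out2 <- cv_r2(X, y, seed = 7, cost = 1000, epsilon = 0)
  expect_identical(out$r2, out2$r2)
  expect_error(cv_r2(X, y, k_folds = 50), "folds")
})

test_that("permuted targets give non-positive cross-validated R2", {
  co <- gen_cohort_features(seed = 5)
  set.seed(6)
  out <- cv_r2(co$X, sample(co$y), n_repeats = 20, seed = 8)
  expect_lte(out$r2_mean, 0 + 2 * out$r2_sd)
})

test_that("exact Shapley reproduces the linear closed form", {
  set.seed(9)
  beta <- c(1, -2, 3, 0.5)
  f <- function(Z) drop(Z %*% beta) + 7
  X <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(NULL, letters[1:4]))
  sh <- exact_shapley(f, X)
  closed <- sweep(X, 2, colMeans(X)) %*% diag(beta)
  expect_lt(max(abs(sh$phi - closed)), 1e-8)
})

test_that("Shapley axioms: efficiency, symmetry, dummy", {
  set.seed(10)
  X <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  X[, 2] <- X[, 1]                       # exact duplicate pair
  f <- function(Z) Z[, 1] * Z[, 2] + sin(Z[, 3]) + 0 * Z[, 4]
  sh <- exact_shapley(f, X)
  # efficiency against the background-mean prediction
  bg <- matrix(colMeans(X), 1, 8, dimnames = list(NULL, colnames(X)))
  expect_lt(max(abs(rowSums(sh$phi) - (f(X) - drop(f(bg))))), 1e-8)
  # symmetry: identical duplicate features receive identical attribution
  expect_equal(sh$phi[, 1], sh$phi[, 2], tolerance = 1e-10)
  # dummy: ignored features get exactly zero
  expect_equal(max(abs(sh$phi[, 4:8])), 0)
  expect_error(exact_shapley(f, matrix(0, 2, 13)), "12 features")
})

test_that("feature ranking is by mean |phi| with alphabetical ties", {
  attr_res <- structure(list(
    phi = NULL, mean_abs = c(b = 0.5, a = 0.5, c = 0.9),
    features = c("b", "a", "c")), class = "attribution_result")
  rk <- rank_features(attr_res)
  expect_equal(rk$feature, c("c", "a", "b"))
  zero <- structure(list(phi = NULL,
                         mean_abs = c(z = 0, m = 0, a = 0),
                         features = c("z", "m", "a")),
                    class = "attribution_result")
  expect_equal(rank_features(zero)$feature, c("a", "m", "z"))
})

test_that("informative features dominate the ranking across seeds", {
  set.seed(11)
  top2_hits <- vapply(1:20, function(s) {
    co <- gen_cohort_features(seed = 100 + s)
    m <- fit_svr_rbf(co$X, co$y)
    rk <- rank_features(exact_shapley(m, co$X))
    all(c("M1", "DLPFC") %in% rk$feature[1:2])
  }, logical(1))
  expect_gte(mean(top2_hits), 0.9)
})

test_that("the cohort generator is reproducible and dimensioned correctly", {
  a <- gen_cohort_features(seed = 12)
  b <- gen_cohort_features(seed = 12)
  expect_identical(a, b)
  expect_equal(dim(a$X), c(38L, 8L))
  expect_true(all(abs(a$u) <= 2))
  single <- gen_cohort_features(informative = "STN", seed = 13)
  expect_gt(abs(cor(single$X[, "STN"], single$y)), 0.8)
})
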