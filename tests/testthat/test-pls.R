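test_that("a single informative channel is recovered exactly with one factor", {
  set.seed(1)
  n <- 12
  x126 <- runif(n, 0.1, 0.9)
  rows <- lapply(seq_len(n), function(i) c(`126` = x126[i]))
  names(rows) <- paste0("s", seq_len(n))
  sp <- toy_spectra(rows, normalization = "tic")
  y <- 5 + 3 * x126
  fit <- fit_pls1(sp, y, 1)
  expect_equal(unname(fit$coef[match("mz_126", paste0("mz_", 30:450))]), 3,
               tolerance = 1e-10)
  expect_equal(predict(fit, sp), y, tolerance = 1e-10)

  # loading concentrated on the informative channel, 421 long, sign positive
  ld <- factor1_loadings(fit)
  expect_equal(nrow(ld), 421)
  expect_equal(which.max(abs(ld$loading)), which(ld$mz == 126))
  expect_gt(ld$loading[ld$mz == 126], 0)
})

test_that("full-factor PLS1 equals the least-squares solution (lm oracle)", {
  set.seed(2)
  for (trial in 1:10) {
    n <- sample(8:20, 1)
    p <- sample(5:min(12, n - 2), 1)
    X <- matrix(rnorm(n * p), n, p)
    if (qr(scale(X, scale = FALSE))$rank < p) next
    beta <- rnorm(p)
    y <- drop(X %*% beta) + rnorm(n, 0, 0.3)
    fit <- fit_pls1(X, y, p)
    ols <- unname(coef(lm(y ~ X))[-1])
    expect_equal(unname(fit$coef), ols, tolerance = 1e-8)
  }
})

test_that("degenerate and rank-deficient designs are signalled", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_pls1(X, rep(2, 10), 2),
               class = "pymbms_error_degenerate_response")

  # rank-1 X cannot give 3 factors
  v <- rnorm(12)
  X1 <- outer(v, c(1, 2, 3, 4))
  err <- tryCatch(fit_pls1(X1, v + rnorm(12, 0, 1e-3), 3),
                  error = function(e) e)
  expect_s3_class(err, "pymbms_error_rank_deficient")
  expect_true(err$achieved_factors >= 1)
})

test_that("NIPALS invariants hold on random fits", {
  set.seed(3)
  for (trial in 1:20) {
    X <- matrix(rnorm(30 * 15), 30, 15)
    y <- rnorm(30)
    fit <- fit_pls1(X, y, 5)
    expect_equal(unname(sqrt(colSums(fit$weights^2))), rep(1, 5),
                 tolerance = 1e-10)
    G <- crossprod(fit$scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
    # prediction of the training mean equals y_mean
    expect_equal(predict(fit, matrix(colMeans(X), 1)), mean(y),
                 tolerance = 1e-12)
  }
})

test_that("calibration RMSE is non-increasing in the factor count", {
  set.seed(4)
  X <- matrix(rnorm(25 * 10), 25, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(25)
  rmse <- vapply(1:6, function(a) {
    f <- fit_pls1(X, y, a)
    sqrt(mean((predict(f, X) - y)^2))
  }, 0)
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("fitting is shift invariant and scale equivariant in y", {
  set.seed(5)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- rnorm(20)
  f0 <- fit_pls1(X, y, 3)
  fshift <- fit_pls1(X, y + 100, 3)
  expect_equal(fshift$coef, f0$coef, tolerance = 1e-9)
  expect_equal(predict(fshift, X), predict(f0, X) + 100, tolerance = 1e-9)
  fscale <- fit_pls1(X, 2 * y, 3)
  expect_equal(fscale$coef, 2 * f0$coef, tolerance = 1e-9)
})

test_that("prediction refuses mismatched normalization states", {
  set <- sim_natural_set(20, seed = 31)
  fit <- fit_pls1(set$avg, set$ref$glucose_dw_pct, 2)
  raw <- set$avg
  attr(raw, "normalization") <- "mean"
  expect_error(predict(fit, raw),
               class = "pymbms_error_inconsistent_normalization")
})

test_that("cross-validation is deterministic, exhaustive for LOO, and honest on noise", {
  set.seed(6)
  # noiseless single-channel relation: RMSECV ~ 0 at 1 factor
  n <- 15
  x <- runif(n)
  X <- cbind(x, matrix(0, n, 4))
  y <- 2 * x
  cv <- cross_validate(X, y, 1, scheme = "loo")
  expect_lt(cv$rmsecv[1], 1e-10)
  expect_equal(attr(cv, "n_fits"), n)

  # pure-noise response: RMSECV cannot beat the response SD
  set.seed(7)
  Xn <- matrix(rnorm(40 * 10), 40, 10)
  yn <- rnorm(40)
  cvn <- cross_validate(Xn, yn, 4, scheme = "loo")
  expect_true(all(cvn$rmsecv >= sd(yn) * 0.9))

  # k-fold determinism and guard
  cva <- cross_validate(Xn, yn, 3, scheme = "kfold", k = 5, seed = 9)
  cvb <- cross_validate(Xn, yn, 3, scheme = "kfold", k = 5, seed = 9)
  expect_identical(cva$rmsecv, cvb$rmsecv)
  expect_error(cross_validate(Xn, yn, 2, scheme = "kfold", k = 50),
               class = "pymbms_error_invalid_folds")
})

test_that("models serialize to JSON and restore with identical predictions", {
  set <- sim_natural_set(25, seed = 41)
  fit <- fit_pls1(set$avg, set$ref$glucose_dw_pct, 3)
  withr::with_tempfile("f", fileext = ".json", {
    write_pls_model(fit, f)
    back <- read_pls_model(f)
    expect_equal(predict(back, set$avg), predict(fit, set$avg),
                 tolerance = 1e-12)
    expect_identical(back$normalization, "tic")
  })
})

test_that("synthetic glucose loadings carry the expected sign structure", {
  set <- sim_natural_set(150, seed = 51)
  fit <- fit_pls1(set$avg, set$ref$glucose_dw_pct, 4)
  ld <- factor1_loadings(fit)
  pick <- function(mz) ld$loading[ld$mz == mz]
  for (mz in c(126, 98, 69)) expect_gt(pick(mz), 0)
  for (mz in c(154, 194, 210)) expect_lt(pick(mz), 0)
})
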