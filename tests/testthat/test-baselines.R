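test_that("least squares recovers a noiseless linear law exactly", {
  set.seed(1)
  d <- data.frame(x1 = runif(60, 1, 5), x2 = runif(60, 1, 5))
  d$y <- 2 * d$x1 - 3 * d$x2 + 20  # positive; lambda fixed at 1 keeps it affine
  fit <- fit_baseline(y ~ x1 + x2, d, "mlr", boxcox_lambda = 1)
  expect_equal(unname(fit$coefficients), c(2, -3), tolerance = 1e-8)
  expect_equal(fit_metrics(d$y, predict(fit, d))$r2, 1)

  olsr <- fit_baseline(y ~ x1 + x2, d, "olsr", boxcox_lambda = 1)
  expect_equal(predict(fit, d), predict(olsr, d))
  expect_error(fit_baseline(y ~ x1 + I(2 * x1), d, "mlr"), "rank")
})

test_that("stepwise keeps truly active inputs and drops noise inputs", {
  set.seed(2)
  n <- 500
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 15 + 2 * d$x2 + rnorm(n, 0, 0.5)
  fit <- fit_baseline(y ~ x1 + x2 + x3, d, "stepwise", boxcox_lambda = 1)
  expect_identical(fit$detail$selected, "x2")
  expect_equal(unname(fit$coefficients), c(0, 2, 0), tolerance = 0.1)

  # pure noise: intercept-only in most replicates
  none <- vapply(1:20, function(s) {
    set.seed(100 + s)
    dn <- data.frame(x1 = rnorm(120), x2 = rnorm(120), y = rnorm(120, 10))
    f <- fit_baseline(y ~ x1 + x2, dn, "stepwise", boxcox_lambda = 1)
    length(f$detail$selected) == 0
  }, logical(1))
  expect_gte(mean(none), 0.9)

  # alpha_enter = 1 admits everything: identical to the full fit
  full <- fit_baseline(y ~ x1 + x2 + x3, d, "stepwise", boxcox_lambda = 1,
                       alpha_enter = 1, alpha_remove = 1)
  mlr <- fit_baseline(y ~ x1 + x2 + x3, d, "mlr", boxcox_lambda = 1)
  expect_equal(full$coefficients, mlr$coefficients, tolerance = 1e-10)
})

test_that("PCR equals least squares at full rank and survives collinearity", {
  set.seed(3)
  d <- data.frame(x1 = runif(80, 0, 10), x2 = runif(80, 0, 10))
  d$y <- 15 + d$x1 + 0.5 * d$x2 + rnorm(80, 0, 0.3)
  pcr <- fit_baseline(y ~ x1 + x2, d, "pcr", boxcox_lambda = 1, n_components = 2)
  mlr <- fit_baseline(y ~ x1 + x2, d, "mlr", boxcox_lambda = 1)
  expect_equal(predict(pcr, d), predict(mlr, d), tolerance = 1e-8)

  d$x3 <- d$x1  # exact duplicate breaks least squares, not PCR
  expect_error(fit_baseline(y ~ x1 + x2 + x3, d, "mlr"), "rank")
  pcr2 <- fit_baseline(y ~ x1 + x2 + x3, d, "pcr", boxcox_lambda = 1,
                       n_components = 2)
  expect_gt(fit_metrics(d$y, predict(pcr2, d))$r2, 0.95)
  expect_error(fit_baseline(y ~ x1 + x2, d, "pcr", n_components = 3), "exceeds")
})

test_that("PLSR reduces to simple regression at p = 1 and to least squares at
           full components", {
  set.seed(4)
  d <- data.frame(x1 = runif(100, 1, 9))
  d$y <- 3 + 0.7 * d$x1 + rnorm(100, 0, 0.2)
  pls <- fit_baseline(y ~ x1, d, "plsr", boxcox_lambda = 1, n_components = 1)
  mlr <- fit_baseline(y ~ x1, d, "mlr", boxcox_lambda = 1)
  expect_equal(predict(pls, d), predict(mlr, d), tolerance = 1e-8)

  d2 <- data.frame(x1 = runif(100, 0, 5), x2 = runif(100, 0, 5),
                   x3 = runif(100, 0, 5))
  d2$y <- 20 + d2$x1 - 2 * d2$x2 + 0.5 * d2$x3 + rnorm(100, 0, 0.2)
  pls3 <- fit_baseline(y ~ x1 + x2 + x3, d2, "plsr", boxcox_lambda = 1,
                       n_components = 3)
  mlr3 <- fit_baseline(y ~ x1 + x2 + x3, d2, "mlr", boxcox_lambda = 1)
  expect_lt(max(abs(predict(pls3, d2) - predict(mlr3, d2))), 1e-6)

  # orthonormal design: one component aligns with the cross-covariance
  n <- 64
  X <- qr.Q(qr(matrix(rnorm(n * 2), n, 2))) * sqrt(n)
  zd <- data.frame(x1 = X[, 1], x2 = X[, 2])
  zd$y <- 20 + 2 * zd$x1 + 0.5 * zd$x2
  p1 <- fit_baseline(y ~ x1 + x2, zd, "plsr", boxcox_lambda = 1, n_components = 1)
  b <- p1$coefficients
  cc <- drop(crossprod(scale(X, scale = FALSE), zd$y - mean(zd$y)))
  expect_equal(unname(b[1] / b[2]), unname(cc[1] / cc[2]), tolerance = 1e-6)
})
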