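test_that("perfect and null relationships give the expected R^2", {
  x <- matrix(1:10, ncol = 1)
  y <- 3 * x[, 1] - 2
  fit <- pls_fit(x, y, ncomp = 1)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(unname(predict(fit, matrix(11))), matrix(31), tolerance = 1e-9)

  # X orthogonal to Y by construction
  xo <- matrix(rep(c(-1, 1), 6), ncol = 1)
  yo <- rep(c(-1, -1, 1, 1), 3)
  expect_lt(pls_fit(xo, yo, ncomp = 1)$r_squared, 1e-20)
})

test_that("NIPALS predictions agree with the eigendecomposition oracle", {
  set.seed(101)
  for (i in 1:8) {
    n <- 20; p <- 8
    X <- matrix(rnorm(n * p), n, p)
    Y <- cbind(3 * X[, 7] + 5 * X[, 8] + rnorm(n, sd = 0.3),
               X[, 7] - 2 * X[, 8] + rnorm(n, sd = 0.3))
    for (A in c(1, 2, 3)) {
      fit <- pls_fit(X, Y, ncomp = A)
      expect_equal(unname(fitted(fit)), unname(pls_oracle(X, Y, A)),
                   tolerance = 1e-6)
    }
  }
})

test_that("NIPALS agrees with mixOmics regression-mode PLS when available", {
  skip_if_not_installed("mixOmics")
  set.seed(7)
  X <- matrix(rnorm(21 * 10), 21, 10,
              dimnames = list(NULL, paste0("p", 1:10)))
  Y <- cbind(2 * X[, 9] + rnorm(21, sd = 0.2), X[, 10] + rnorm(21, sd = 0.2))
  fit <- pls_fit(X, Y, ncomp = 2)
  mo <- mixOmics::pls(X, Y, ncomp = 2, mode = "regression", scale = TRUE)
  pr <- predict(mo, X)$predict[, , 2]
  expect_equal(unname(fitted(fit)), unname(pr), tolerance = 1e-6)
})

test_that("input validation catches degenerate problems", {
  X <- matrix(rnorm(15), 5, 3); X[, 2] <- 7
  expect_error(pls_fit(X, rnorm(5), ncomp = 1), "constant")
  expect_error(pls_fit(matrix(rnorm(20), 5), rnorm(5), ncomp = 5), "ncomp")
  Xn <- matrix(rnorm(20), 5); Xn[1] <- NA
  expect_error(pls_fit(Xn, rnorm(5), ncomp = 1), "finite")
})

test_that("VIP satisfies its closed forms and normalisation", {
  # p = 1: normalisation forces VIP = 1
  x <- matrix(rnorm(10), ncol = 1)
  f1 <- pls_fit(x, 2 * x[, 1] + rnorm(10, sd = 0.1), ncomp = 1)
  expect_equal(unname(vip(f1)$vip), 1.0, tolerance = 1e-10)

  # one-component model with w = (1, 0): VIP = (sqrt(2), 0)
  n <- 12
  x2 <- rep(c(-1, 1), n / 2)
  x1 <- unname(residuals(lm(rnorm(n) ~ x2)))  # exactly orthogonal to x2
  X <- cbind(x1, x2)
  y <- x1                       # only column 1 carries signal
  f2 <- pls_fit(X, y, ncomp = 1)
  expect_equal(unname(f2$weights[, 1]), c(1, 0), tolerance = 1e-6)
  expect_equal(unname(vip(f2)$vip), c(sqrt(2), 0), tolerance = 1e-5)

  # sum of squared VIPs equals p on random models
  set.seed(33)
  for (i in 1:10) {
    X <- matrix(rnorm(21 * 10), 21, 10)
    Y <- cbind(rnorm(21), rnorm(21))
    A <- sample(1:4, 1)
    v <- vip(pls_fit(X, Y, ncomp = A))
    expect_equal(sum(v$vip^2), 10, tolerance = 1e-8)
  }
})

test_that("VIP screening is strict, sorted, and order-invariant", {
  sel <- screen_by_vip(TABLE2_VIP, threshold = 1.0)
  expect_identical(sel, c("10", "9"))
  expect_identical(screen_by_vip(rep(0.5, 10)), character(0))
  expect_identical(screen_by_vip(c(a = 1.0, b = 1.2), threshold = 1.0), "b")

  set.seed(12)
  X <- matrix(rnorm(21 * 10), 21, 10,
              dimnames = list(NULL, as.character(1:10)))
  Y <- 2 * X[, 9] + 3 * X[, 10] + rnorm(21, sd = 0.2)
  perm <- sample(10)
  v1 <- vip(pls_fit(X, Y, ncomp = 2))$vip
  v2 <- vip(pls_fit(X[, perm], Y, ncomp = 2))$vip
  expect_equal(v2[as.character(1:10)], v1, tolerance = 1e-9)
})

test_that("adjusted R^2 follows the degrees-of-freedom formula", {
  expect_equal(adjusted_r_squared(1, 21, 10), 1)
  expect_equal(adjusted_r_squared(0.902, 21, 10), 0.804)
  expect_equal(adjusted_r_squared(0, 21, 10), -1.0)
  expect_error(adjusted_r_squared(0.5, 11, 10), "n > p")
})
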