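test_that("training is deterministic and converges on easy targets", {
  set.seed(400)
  X <- matrix(runif(20 * 3), 20, 3)

  # constant target: network output collapses to the constant
  yc <- rep(5, 20)
  mc <- train_bpann(X, yc, epochs = 1000, seed = 2)
  expect_lt(mc$trace$mse[1000], 1e-4)
  expect_equal(unname(predict(mc, X)[, 1]), yc, tolerance = 1e-2)

  # bit-reproducible for a fixed seed
  m1 <- train_bpann(X, X[, 1], epochs = 50, seed = 9)
  m2 <- train_bpann(X, X[, 1], epochs = 50, seed = 9)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$trace$mse, m2$trace$mse)

  # linear relation: the training error trends downward over the run
  ml <- train_bpann(X, X[, 1], epochs = 500, seed = 3)
  win <- function(e) mean(ml$trace$mse[e:(e + 99)])
  starts <- seq(1, 401, by = 100)
  expect_true(all(diff(sapply(starts, win)) < 0))
  expect_equal(nrow(ml$trace), 500L)
})

test_that("backprop gradients match central differences", {
  set.seed(77)
  n <- 5; p <- 3; h <- 2; m <- 1
  X <- matrix(runif(n * p), n, p)
  Y <- matrix(runif(n * m), n, m)
  unpack <- function(th) {
    W1 <- matrix(th[1:(p * h)], p, h)
    b1 <- th[p * h + 1:h]
    W2 <- matrix(th[p * h + h + 1:(h * m)], h, m)
    b2 <- th[p * h + h + h * m + 1:m]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  loss <- function(th) {
    pa <- unpack(th)
    H <- 1 / (1 + exp(-(sweep(X %*% pa$W1, 2, pa$b1, "+"))))
    O <- sweep(H %*% pa$W2, 2, pa$b2, "+")
    mean((O - Y)^2)
  }
  analytic <- function(th) {
    pa <- unpack(th)
    H <- 1 / (1 + exp(-(sweep(X %*% pa$W1, 2, pa$b1, "+"))))
    O <- sweep(H %*% pa$W2, 2, pa$b2, "+")
    gO <- 2 * (O - Y) / (n * m)
    gH <- gO %*% t(pa$W2) * H * (1 - H)
    c(crossprod(X, gH), colSums(gH), crossprod(H, gO), colSums(gO))
  }
  for (i in 1:5) {
    th <- runif(p * h + h + h * m + m, -1, 1)
    expect_equal(analytic(th), numeric_gradient(loss, th), tolerance = 1e-6)
  }
})

test_that("training aborts with a diagnostic on divergence", {
  set.seed(1)
  X <- matrix(runif(40), 10, 4)
  expect_error(train_bpann(X, rnorm(10), lr = 1e4, momentum = 0.99,
                           epochs = 200, seed = 1),
               "epoch")
})

test_that("MIV closed forms hold for hand-built networks", {
  # identity-like linear network y = x1
  net <- bpann_network(W1 = matrix(c(1, 0, 0), 3, 1), b1 = 0,
                       W2 = matrix(1), b2 = 0, activation = "identity")
  X <- matrix(runif(30, 1, 5), 10, 3)
  r <- miv(net, X, delta = 0.10)
  expect_equal(unname(r$miv[1]), 0.2 * mean(X[, 1]), tolerance = 1e-12)
  # variables with zero first-layer weight have exactly zero impact
  expect_identical(unname(r$miv[2]), 0)
  expect_identical(unname(r$miv[3]), 0)
  expect_identical(r$iv, r$miv * nrow(X))

  # purely linear multi-path network: MIV_j proportional to path weights
  W1 <- matrix(c(2, -1, 0.5, 1, 3, -2), 3, 2)
  W2 <- matrix(c(0.7, -0.3), 2, 1)
  net2 <- bpann_network(W1, c(0, 0), W2, 0, activation = "identity")
  r2 <- miv(net2, X, delta = 0.10)
  path <- as.vector(W1 %*% W2)
  expect_equal(unname(r2$miv), 0.2 * colMeans(X) * path, tolerance = 1e-10)

  expect_error(miv(net, X, delta = 1.5), "delta")
})

test_that("MIV respects a zero-weight input after real training", {
  set.seed(21)
  X <- matrix(runif(60), 20, 3)
  m <- train_bpann(X, X[, 1] + 2 * X[, 2], epochs = 200, seed = 5)
  m$W1[3, ] <- 0   # sever every pathway of input 3
  r <- miv(m, X)
  expect_identical(unname(r$miv[3]), 0)
})

test_that("variable ranking follows signed MIV with index tie-breaks", {
  expect_identical(rank_variables(TABLE2_MIV, top_k = 2), c("10", "9"))
  # |MIV| ranking instead picks peak 1 (-0.256) over peak 9 (0.255)
  expect_identical(rank_variables(TABLE2_MIV, top_k = 2, use = "abs"),
                   c("10", "1"))
  expect_identical(rank_variables(rep(0.3, 5), top_k = 3),
                   c("1", "2", "3"))
  expect_identical(rank_variables(c(a = 1, b = 3, c = 2), top_k = 3),
                   c("b", "c", "a"))
})
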