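.bpann_act <- function(name) {
  switch(name,
    logistic = list(f = function(z) 1 / (1 + exp(-z)),
                    df = function(h) h * (1 - h)),
    tanh = list(f = tanh, df = function(h) 1 - h^2),
    identity = list(f = identity, df = function(h) 1 + 0 * h),
    stop("unknown activation '", name, "'"))
}

.minmax <- function(M) {
  lo <- apply(M, 2L, min); hi <- apply(M, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant columns map to 0
  list(min = lo, range = rng)
}

#' Assemble a feed-forward network from explicit weights
#'
#' Low-level constructor for a single-hidden-layer network
#' `y = W2' a(W1' x + b1) + b2` with optional input/output min-max scaling.
#' Useful for building networks with known closed-form behaviour (e.g. a
#' purely linear network) to validate impact-value computations.
#'
#' @param W1 p x h input-to-hidden weight matrix.
#' @param b1 Hidden bias vector (length h).
#' @param W2 h x m hidden-to-output weight matrix.
#' @param b2 Output bias vector (length m).
#' @param activation Hidden activation: `"logistic"`, `"tanh"` or
#'   `"identity"`.
#' @param x_min,x_range,y_min,y_range Optional scaling parameters; defaults
#'   give identity scaling.
#' @return Object of class `bpann`.
#' @export
bpann_network <- function(W1, b1, W2, b2, activation = "identity",
                          x_min = rep(0, nrow(W1)),
                          x_range = rep(1, nrow(W1)),
                          y_min = rep(0, ncol(W2)),
                          y_range = rep(1, ncol(W2))) {
  stopifnot(ncol(W1) == length(b1), ncol(W1) == nrow(W2),
            ncol(W2) == length(b2))
  structure(list(W1 = as.matrix(W1), b1 = b1, W2 = as.matrix(W2), b2 = b2,
                 activation = activation,
                 x_min = x_min, x_range = x_range,
                 y_min = y_min, y_range = y_range,
                 trace = NULL, epochs = 0L, seed = NA_integer_),
            class = "bpann")
}

.bpann_forward <- function(model, X) {
  act <- .bpann_act(model$activation)
  Xs <- sweep(sweep(as.matrix(X), 2L, model$x_min), 2L, model$x_range, "/")
  H <- act$f(sweep(Xs %*% model$W1, 2L, model$b1, "+"))
  Os <- sweep(H %*% model$W2, 2L, model$b2, "+")
  list(Xs = Xs, H = H, Os = Os,
       Y = sweep(sweep(Os, 2L, model$y_range, "*"), 2L, model$y_min, "+"))
}

#' Train a back-propagation neural network
#'
#' Classic three-layer BP-ANN: `hidden` sigmoid units, linear output,
#' trained by full-batch gradient descent on the mean squared error with
#' optional momentum. Inputs and outputs are min-max scaled to `[0, 1]`
#' internally. Training is deterministic for a fixed `seed` (weights are
#' initialised uniformly on `[-0.5, 0.5]`); the mean squared error and
#' gradient norm are recorded every epoch as training diagnostics.
#'
#' @param X Numeric n x p input matrix (n >= 4, finite).
#' @param Y Numeric response vector or n x m matrix.
#' @param hidden Number of hidden units ("knots"), default 3.
#' @param epochs Training epochs, default 5000.
#' @param lr Learning rate on the scaled blocks, default 0.05.
#' @param momentum Momentum coefficient, default 0.9 (set 0 to disable).
#' @param activation Hidden activation, default `"logistic"`.
#' @param seed Integer seed for weight initialisation (required for
#'   reproducibility).
#' @return Object of class `bpann`; `$trace` is a data frame with `epoch`,
#'   `mse` (on the scaled blocks) and `grad_norm`.
#' @export
train_bpann <- function(X, Y, hidden = 3L, epochs = 5000L, lr = 0.05,
                        momentum = 0.9, activation = "logistic", seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  stopifnot(n >= 4, nrow(Y) == n, epochs >= 1,
            all(is.finite(X)), all(is.finite(Y)))
  act <- .bpann_act(activation)
  sx <- .minmax(X); sy <- .minmax(Y)
  Xs <- sweep(sweep(X, 2L, sx$min), 2L, sx$range, "/")
  Ys <- sweep(sweep(Y, 2L, sy$min), 2L, sy$range, "/")

  rs <- .preserve_rng(seed)
  on.exit(.restore_rng(rs), add = TRUE)
  W1 <- matrix(stats::runif(p * hidden, -0.5, 0.5), p, hidden)
  b1 <- stats::runif(hidden, -0.5, 0.5)
  W2 <- matrix(stats::runif(hidden * m, -0.5, 0.5), hidden, m)
  b2 <- stats::runif(m, -0.5, 0.5)
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0

  mse <- numeric(epochs); gnorm <- numeric(epochs)
  for (e in seq_len(epochs)) {
    H <- act$f(sweep(Xs %*% W1, 2L, b1, "+"))
    O <- sweep(H %*% W2, 2L, b2, "+")
    E <- O - Ys
    mse[e] <- mean(E^2)
    if (!is.finite(mse[e])) {
      stop("training diverged (non-finite loss) at epoch ", e)
    }
    # gradients of MSE = mean over n*m of squared error
    gO <- 2 * E / (n * m)
    gW2 <- crossprod(H, gO); gb2 <- colSums(gO)
    gH <- gO %*% t(W2) * act$df(H)
    gW1 <- crossprod(Xs, gH); gb1 <- colSums(gH)
    gnorm[e] <- sqrt(sum(gW1^2) + sum(gb1^2) + sum(gW2^2) + sum(gb2^2))
    vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
    vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
    vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
    vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
  }
  rownames(W1) <- colnames(X)
  model <- bpann_network(W1, b1, W2, b2, activation = activation,
                         x_min = sx$min, x_range = sx$range,
                         y_min = sy$min, y_range = sy$range)
  model$trace <- data.frame(epoch = seq_len(epochs), mse = mse,
                            grad_norm = gnorm)
  model$epochs <- as.integer(epochs)
  model$seed <- as.integer(seed)
  model
}

#' @export
predict.bpann <- function(object, newdata, ...) {
  .bpann_forward(object, newdata)$Y
}

#' @export
print.bpann <- function(x, ...) {
  cat("BP-ANN:", nrow(x$W1), "inputs ->", ncol(x$W1), "hidden (",
      x$activation, ") ->", ncol(x$W2), "outputs\n")
  if (!is.null(x$trace)) {
    cat("  trained", x$epochs, "epochs; final scaled MSE =",
        formatC(x$trace$mse[nrow(x$trace)], format = "e", digits = 3), "\n")
  }
  invisible(x)
}

#' @export
plot.bpann <- function(x, ...) {
  if (is.null(x$trace)) stop("no training trace to plot")
  graphics::par(mfrow = c(1, 2))
  graphics::plot(x$trace$epoch, x$trace$mse, type = "l", log = "y",
                 xlab = "epoch", ylab = "MSE (scaled)",
                 main = "Training error", ...)
  graphics::plot(x$trace$epoch, x$trace$grad_norm, type = "l", log = "y",
                 xlab = "epoch", ylab = "gradient norm",
                 main = "Gradient magnitude", ...)
  invisible(x)
}

#' Mean impact value (MIV) of each input variable
#'
#' For each input `j` the training matrix is perturbed to `X+` (column `j`
#' scaled by `1 + delta`) and `X-` (scaled by `1 - delta`); the impact value
#' `IV_j` is the sum over samples (and outputs) of the prediction difference,
#' and the mean impact value is `MIV_j = IV_j / n` with `n` the number of
#' observations.
#'
#' @param model A fitted or assembled [bpann] model.
#' @param X Input matrix the impacts are evaluated on (typically the
#'   training data).
#' @param delta Relative perturbation, in `(0, 1)`; default 0.10.
#' @return Object of class `miv_result`: `iv`, `miv` (named), `n`,
#'   `ranking` (ids by signed MIV, decreasing) and `ranking_abs` (ids by
#'   absolute MIV, decreasing); ties broken by lower variable index.
#' @export
miv <- function(model, X, delta = 0.10) {
  stopifnot(inherits(model, "bpann"))
  if (delta <= 0 || delta >= 1) stop("delta must be in (0, 1)")
  X <- as.matrix(X)
  p <- nrow(model$W1)
  stopifnot(ncol(X) == p)
  n <- nrow(X)
  iv <- numeric(p)
  for (j in seq_len(p)) {
    Xp <- X; Xp[, j] <- X[, j] * (1 + delta)
    Xm <- X; Xm[, j] <- X[, j] * (1 - delta)
    iv[j] <- sum(predict(model, Xp) - predict(model, Xm))
  }
  ids <- rownames(model$W1)
  if (is.null(ids)) ids <- as.character(seq_len(p))
  names(iv) <- ids
  mv <- iv / n
  ord_signed <- order(-mv, seq_len(p))
  ord_abs <- order(-abs(mv), seq_len(p))
  structure(list(iv = iv, miv = mv, n = n, delta = delta,
                 ranking = ids[ord_signed], ranking_abs = ids[ord_abs]),
            class = "miv_result")
}

#' @export
print.miv_result <- function(x, ...) {
  cat("Mean impact values (delta = ", x$delta, ", n = ", x$n, ")\n",
      sep = "")
  print(round(x$miv, 4))
  cat("ranking (signed):", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Initialisation-averaged mean impact values
#'
#' MIV inherits variance from the random weight initialisation of a single
#' trained network. This convenience wrapper trains `restarts` networks on
#' the same data (seeds `seed + 1 ... seed + restarts`) and averages their
#' per-variable mean impact values, which reports the
#' initialisation-independent component of the impact.
#'
#' @param X,Y Training blocks as in [train_bpann()].
#' @param restarts Number of independently initialised networks (5).
#' @param delta Perturbation fraction passed to [miv()].
#' @param seed Base seed.
#' @inheritParams train_bpann
#' @return A `miv_result` whose `iv`/`miv` are averages over the restarts.
#' @export
miv_ensemble <- function(X, Y, restarts = 5L, delta = 0.10, hidden = 3L,
                         epochs = 5000L, lr = 0.05, momentum = 0.9,
                         activation = "logistic", seed = 1L) {
  stopifnot(restarts >= 1)
  acc <- NULL
  for (r in seq_len(restarts)) {
    model <- train_bpann(X, Y, hidden = hidden, epochs = epochs, lr = lr,
                         momentum = momentum, activation = activation,
                         seed = seed + r)
    m <- miv(model, X, delta = delta)
    acc <- if (is.null(acc)) m$miv else acc + m$miv
  }
  mv <- acc / restarts
  p <- length(mv)
  ord_signed <- order(-mv, seq_len(p))
  ord_abs <- order(-abs(mv), seq_len(p))
  structure(list(iv = mv * nrow(as.matrix(X)), miv = mv,
                 n = nrow(as.matrix(X)), delta = delta,
                 restarts = as.integer(restarts),
                 ranking = names(mv)[ord_signed],
                 ranking_abs = names(mv)[ord_abs]),
            class = "miv_result")
}

#' Top variables by mean impact value
#'
#' @param r A `miv_result`, or a named numeric vector of MIV values.
#' @param top_k How many variables to return (`<= p`).
#' @param use `"signed"` (default) ranks by the MIV itself, largest first —
#'   the rule that keeps positively toxicity-associated peaks on top;
#'   `"abs"` ranks by absolute MIV. Ties are broken by lower variable index.
#' @return Character vector of the `top_k` ids.
#' @export
rank_variables <- function(r, top_k, use = c("signed", "abs")) {
  use <- match.arg(use)
  v <- if (inherits(r, "miv_result")) r$miv else r
  if (is.null(names(v))) names(v) <- as.character(seq_along(v))
  stopifnot(top_k <= length(v), top_k >= 1)
  key <- if (use == "signed") v else abs(v)
  names(v)[order(-key, seq_along(v))][seq_len(top_k)]
}
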