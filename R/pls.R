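#' Partial least squares regression (NIPALS, PLS2)
#'
#' Fits a two-block predictive PLS model relating a fingerprint matrix `X`
#' (samples x peaks) to one or more toxicity endpoints `Y` (e.g. per-sample
#' mean ALT and AST). Both blocks are mean-centered and scaled to unit
#' variance (autoscaling) before extraction; components are extracted by the
#' NIPALS algorithm with deflation of both blocks.
#'
#' When `ncomp = NULL` the number of components is chosen by leave-one-out
#' cross-validation of Q^2 (1 - PRESS/SS) with a parsimony rule: the
#' smallest A whose Q^2 lies within 0.02 of the maximum, capped at
#' `min(5, n - 1, p)`.
#'
#' @param X Numeric n x p predictor matrix (n >= 3; no zero-variance
#'   column).
#' @param Y Numeric response vector or n x m matrix.
#' @param ncomp Number of latent components, or `NULL` for LOO-CV choice.
#' @param tol NIPALS convergence tolerance on the change of the weight
#'   vector (default 1e-10).
#' @param max_iter Maximum NIPALS inner iterations per component (500).
#' @return Object of class `pls_nipals` with elements `weights` (p x A,
#'   unit-norm columns), `loadings_x`, `loadings_y`, `scores`,
#'   `coefficients` (regression coefficients on the original scale),
#'   `x_mean`, `x_scale`, `y_mean`, `y_scale`, `ssy` (explained Y sum of
#'   squares per component on the scaled block), `r_squared` (overall, on
#'   the scaled block), `fitted`, `ncomp`, and `cv` (Q^2 table when LOO-CV
#'   was used).
#' @seealso [vip()], [screen_by_vip()]
#' @export
pls_fit <- function(X, Y, ncomp = NULL, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("X and Y must be finite")
  }
  stopifnot(nrow(Y) == n, n >= 3)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(p))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(m))

  x_mean <- colMeans(X); x_scale <- apply(X, 2L, stats::sd)
  y_mean <- colMeans(Y); y_scale <- apply(Y, 2L, stats::sd)
  if (any(x_scale == 0)) {
    stop("constant column(s) in X: ",
         paste(colnames(X)[x_scale == 0], collapse = ", "))
  }
  if (any(y_scale == 0)) stop("constant column(s) in Y")
  a_max <- min(n - 1L, p)

  cv <- NULL
  if (is.null(ncomp)) {
    a_try <- min(5L, a_max)
    press <- matrix(NA_real_, n, a_try)
    for (i in seq_len(n)) {
      fi <- tryCatch(
        pls_fit(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                ncomp = min(a_try, n - 2L, p), tol = tol,
                max_iter = max_iter),
        error = function(e) NULL)
      if (is.null(fi)) next
      for (a in seq_len(fi$ncomp)) {
        pr <- predict(fi, X[i, , drop = FALSE], ncomp = a)
        # residual on the full-data autoscale so folds are comparable
        press[i, a] <- sum(((Y[i, ] - pr) / y_scale)^2)
      }
    }
    ss <- sum(scale(Y)^2) / n
    q2 <- 1 - colMeans(press, na.rm = TRUE) / ss
    # parsimony rule: smallest A whose Q^2 is within 0.02 of the best
    ncomp <- min(which(q2 >= max(q2, na.rm = TRUE) - 0.02))
    cv <- data.frame(ncomp = seq_along(q2), q2 = q2)
  }
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > a_max) {
    stop("ncomp must be between 1 and min(n-1, p) = ", a_max)
  }

  Xs <- scale(X, center = x_mean, scale = x_scale)
  Ys <- scale(Y, center = y_mean, scale = y_scale)
  Xr <- Xs; Yr <- Ys
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, m, ncomp); Tm <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp)
  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    # degenerate X'Y = 0: any direction explains zero Y variance; use a
    # fixed one so the fit stays deterministic
    if (nv == 0) rep(1 / sqrt(length(v)), length(v)) else v / nv
  }
  for (a in seq_len(ncomp)) {
    u <- Yr[, which.max(apply(Yr, 2L, stats::var))]
    w <- unit(crossprod(Xr, u))
    for (it in seq_len(max_iter)) {
      tvec <- Xr %*% w
      cvec <- crossprod(Yr, tvec) / sum(tvec^2)
      if (sum(cvec^2) == 0) break
      u <- Yr %*% cvec / sum(cvec^2)
      w_new <- unit(crossprod(Xr, u))
      if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; break }
      w <- w_new
    }
    tvec <- Xr %*% w
    tt <- sum(tvec^2)
    pvec <- crossprod(Xr, tvec) / tt
    cvec <- crossprod(Yr, tvec) / tt
    W[, a] <- w; P[, a] <- pvec; C[, a] <- cvec; Tm[, a] <- tvec
    ssy[a] <- tt * sum(cvec^2)  # Y sum of squares explained by component a
    Xr <- Xr - tcrossprod(tvec, pvec)
    Yr <- Yr - tcrossprod(tvec, cvec)
  }
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(C) <- colnames(Y)

  # B on the scaled blocks, then back-transformed to the original scale
  R <- W %*% solve(crossprod(P, W))
  Bs <- R %*% t(C)
  B <- sweep(sweep(Bs, 1L, x_scale, "/"), 2L, y_scale, "*")
  intercept <- y_mean - crossprod(B, x_mean)[, 1L]
  fitted <- sweep(X %*% B, 2L, intercept, "+")
  r2 <- 1 - sum((Ys - (fitted - matrix(y_mean, n, m, byrow = TRUE)) %*%
                   diag(1 / y_scale, m))^2) / sum(Ys^2)

  structure(list(weights = W, loadings_x = P, loadings_y = C, scores = Tm,
                 coefficients = B, intercept = intercept,
                 x_mean = x_mean, x_scale = x_scale,
                 y_mean = y_mean, y_scale = y_scale,
                 ssy = ssy, r_squared = r2, fitted = fitted, y = Y,
                 ncomp = ncomp, n = n, p = p, m = m, cv = cv,
                 x_names = colnames(X), y_names = colnames(Y)),
            class = "pls_nipals")
}

#' @export
predict.pls_nipals <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$p, ncomp >= 1, ncomp <= object$ncomp)
  if (ncomp == object$ncomp) {
    B <- object$coefficients; b0 <- object$intercept
  } else {
    W <- object$weights[, seq_len(ncomp), drop = FALSE]
    P <- object$loadings_x[, seq_len(ncomp), drop = FALSE]
    C <- object$loadings_y[, seq_len(ncomp), drop = FALSE]
    Bs <- W %*% solve(crossprod(P, W)) %*% t(C)
    B <- sweep(sweep(Bs, 1L, object$x_scale, "/"), 2L, object$y_scale, "*")
    b0 <- object$y_mean - crossprod(B, object$x_mean)[, 1L]
  }
  sweep(newdata %*% B, 2L, b0, "+")
}

#' @export
coef.pls_nipals <- function(object, ...) object$coefficients

#' @export
fitted.pls_nipals <- function(object, ...) object$fitted

#' @export
residuals.pls_nipals <- function(object, ...) object$y - object$fitted

#' @export
print.pls_nipals <- function(x, ...) {
  cat("PLS regression (NIPALS):", x$n, "samples,", x$p, "predictors,",
      x$m, "response(s),", x$ncomp, "component(s)\n")
  cat("  R^2 =", formatC(x$r_squared, format = "f", digits = 3), "\n")
  if (!is.null(x$cv)) {
    cat("  LOO-CV Q^2:",
        paste(formatC(x$cv$q2, format = "f", digits = 3), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.pls_nipals <- function(object, ...) {
  print(object)
  v <- vip(object)
  cat("  adjusted R^2 =",
      formatC(adjusted_r_squared(object$r_squared, object$n, object$p),
              format = "f", digits = 3), "\n")
  cat("VIP values:\n")
  print(round(v$vip, 3))
  invisible(object)
}

#' Variable importance for the projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)` where `SSY_a` is the
#' Y sum of squares explained by component `a` and `w` are the unit-norm
#' NIPALS weights. The scores satisfy `sum_j VIP_j^2 = p`.
#'
#' @param m A fitted [pls_fit()] model.
#' @param threshold Screening threshold, default 1.0.
#' @return Object of class `vip_result`: `vip` (named vector), `threshold`,
#'   `selected` (ids with VIP strictly above the threshold, decreasing),
#'   `r_squared`, `adjusted_r_squared`.
#' @export
vip <- function(m, threshold = 1.0) {
  stopifnot(inherits(m, "pls_nipals"))
  if (sum(m$ssy) <= 0) stop("model explains no Y variance; VIP undefined")
  w2 <- m$weights^2
  v <- sqrt(m$p * as.vector(w2 %*% m$ssy) / sum(m$ssy))
  names(v) <- m$x_names
  structure(list(vip = v, threshold = threshold,
                 selected = screen_by_vip(v, threshold),
                 r_squared = m$r_squared,
                 adjusted_r_squared =
                   if (m$n > m$p + 1) adjusted_r_squared(m$r_squared, m$n, m$p)
                   else NA_real_),
            class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  cat("VIP screening (threshold >", x$threshold, ")\n")
  print(round(x$vip, 3))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Screen variables by VIP threshold
#'
#' @param v A `vip_result`, or a named numeric vector of VIP values.
#' @param threshold Positive threshold; selection is strict (`vip >
#'   threshold`), so a value exactly at the threshold is excluded.
#' @return Character vector of selected ids, ordered by decreasing VIP.
#' @export
screen_by_vip <- function(v, threshold = 1.0) {
  stopifnot(threshold > 0)
  if (inherits(v, "vip_result")) v <- v$vip
  if (is.null(names(v))) names(v) <- as.character(seq_along(v))
  sel <- v[v > threshold]
  names(sel)[order(-sel)]
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)`; may be negative.
#'
#' @param r2 R-squared in `[0, 1]`.
#' @param n Number of samples (must exceed `p + 1`).
#' @param p Number of predictors.
#' @return Adjusted R-squared.
#' @export
adjusted_r_squared <- function(r2, n, p) {
  if (n <= p + 1) stop("adjusted R^2 requires n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}
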