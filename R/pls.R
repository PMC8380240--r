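#' Fit a PLS(-DA) model by NIPALS
#'
#' Partial least squares regression of a class-coded response on a feature
#' matrix, the discriminant engine of the pipeline. X is autoscaled (mean 0,
#' unit variance; constants stored in the model so that scaling is always
#' refit on the training split, never on held-out data) and Y is centered.
#' Components are extracted by NIPALS with deflation of both blocks; for a
#' multi-column Y (PLS2) the inner loop iterates to convergence (tolerance
#' `1e-10`, at most 500 iterations, otherwise an error). The regression
#' vector is recoverable as `W (P'W)^-1 Q'`. Class membership is coded 0/1,
#' so the natural decision threshold on a predicted y is 0.5.
#'
#' @param X raw (unscaled) numeric matrix, samples x features.
#' @param Y numeric response: vector or 0/1 indicator matrix.
#' @param n_lv number of latent variables, at most `min(n - 1, p)`. If the
#'   Y residual vanishes earlier, the model stops with fewer components.
#' @param tol,max_iter NIPALS convergence control (PLS2 inner loop).
#' @return object of class `pls_model` with weights `W`, x-loadings `P`,
#'   y-loadings `Q`, scores `T`, per-component explained y-variance `ssy`,
#'   scaling constants and the achieved `n_lv`.
#' @export
fit_pls <- function(X, Y, n_lv, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stopf("X and Y row counts differ")
  if (n_lv < 1 || n_lv > min(n - 1, p))
    stopf("n_lv must be in [1, min(n-1, p)] = [1, %d]", min(n - 1, p))
  x_center <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  x_scale <- ifelse(x_sd < .Machine$double.eps^0.5, 1, x_sd)
  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center)

  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, q, n_lv); Tm <- matrix(0, n, n_lv)
  ssy <- numeric(n_lv)
  a_done <- 0L
  for (a in seq_len(n_lv)) {
    if (sum(Yc^2) < tol) break  # response fully explained
    if (q == 1) {
      w <- crossprod(Xc, Yc)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      t_a <- as.numeric(Xc %*% w)
    } else {
      u <- Yc[, which.max(colSums(Yc^2))]
      t_old <- rep(Inf, n)
      for (it in seq_len(max_iter)) {
        w <- crossprod(Xc, u)[, 1]
        w <- w / sqrt(sum(w^2))
        t_a <- as.numeric(Xc %*% w)
        qv <- crossprod(Yc, t_a)[, 1] / sum(t_a^2)
        u <- as.numeric(Yc %*% qv) / sum(qv^2)
        if (sqrt(sum((t_a - t_old)^2)) < tol * sqrt(sum(t_a^2))) break
        if (it == max_iter)
          stopf("NIPALS did not converge within %d iterations for LV %d",
                max_iter, a)
        t_old <- t_a
      }
    }
    tt <- sum(t_a^2)
    if (tt < tol) break
    p_a <- crossprod(Xc, t_a)[, 1] / tt
    q_a <- crossprod(Yc, t_a)[, 1] / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    Yc <- Yc - tcrossprod(t_a, q_a)
    W[, a] <- w; P[, a] <- p_a; Q[, a] <- q_a; Tm[, a] <- t_a
    ssy[a] <- tt * sum(q_a^2)   # y-variance captured by this component
    a_done <- a
  }
  if (a_done == 0L) stopf("no usable PLS component (X carries no y signal)")
  keep <- seq_len(a_done)
  structure(list(n_lv = a_done,
                 W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
                 Q = Q[, keep, drop = FALSE], T = Tm[, keep, drop = FALSE],
                 ssy = ssy[keep],
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center,
                 feature_names = colnames(X), class_names = colnames(Y)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d LV(s), %d features, %d response column(s)\n",
              x$n_lv, nrow(x$W), nrow(x$Q)))
  invisible(x)
}

# Regression coefficients on the scaled space using the first `a` LVs.
pls_coefficients <- function(model, a = model$n_lv) {
  keep <- seq_len(a)
  W <- model$W[, keep, drop = FALSE]
  P <- model$P[, keep, drop = FALSE]
  Q <- model$Q[, keep, drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' Predict from a PLS model
#'
#' New data are scaled with the model's stored centers and scales, then
#' multiplied by the regression vector; no thresholding is applied (the
#' continuous predicted y is what the ternary mapping consumes).
#'
#' @param object a `pls_model`.
#' @param newdata raw matrix over the model's features.
#' @param ncomp number of latent variables to use (default: all fitted).
#' @param ... unused.
#' @return matrix of predicted y, samples x response columns (a plain
#'   vector for a single-column response).
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$n_lv, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$W))
    stopf("feature count mismatch: model has %d, newdata has %d",
          nrow(object$W), ncol(newdata))
  Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  B <- pls_coefficients(object, ncomp)
  yhat <- sweep(Xs %*% B, 2, object$y_center, "+")
  if (ncol(yhat) == 1) as.numeric(yhat) else yhat
}

# Predictions for every LV count 1..n_lv at once (matrix n x n_lv for a
# univariate y). Used by the inner CV loop.
predict_pls_all <- function(model, newdata) {
  vapply(seq_len(model$n_lv), function(a)
    as.numeric(predict(model, newdata, ncomp = a)),
    numeric(nrow(as.matrix(newdata))))
}

#' Variable importance in projection (VIP)
#'
#' `vip_f = sqrt( p * sum_a ssy_a * w_fa^2 / sum_a ssy_a )` with unit-norm
#' weight vectors and `ssy_a` the y-variance explained by component `a`.
#' The squared scores average to exactly 1 over features; features with
#' VIP > 1 are the conventional discriminant selection.
#'
#' @param model a `pls_model`.
#' @return named numeric vector of VIP scores per feature.
#' @export
vip <- function(model) {
  p <- nrow(model$W)
  w2 <- model$W^2   # columns already unit norm
  v <- sqrt(p * as.numeric(w2 %*% model$ssy) / sum(model$ssy))
  stats::setNames(v, model$feature_names)
}
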