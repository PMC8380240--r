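# Predict from an eps-SVR fit; a model whose epsilon tube encloses every
# training point has no support vectors and its solution is the constant
# offset -rho, which predict.svm refuses to evaluate.
svr_predict <- function(fit, newx) {
  if (fit$tot.nSV == 0) return(rep(-fit$rho, nrow(newx)))
  as.numeric(stats::predict(fit, newx))
}

#' QC-SVRC: support-vector regression of the QC drift trend
#'
#' Fits an epsilon-insensitive support-vector regression (RBF kernel) of QC
#' intensity on injection order for one feature in one batch, the
#' non-parametric QC-based drift model used for within-batch correction.
#' The regularization constant `C` is fixed at the median QC intensity of
#' the feature; the tube half-width `epsilon` and kernel width `gamma` are
#' chosen on a grid (`epsilon`: `n_eps` linear steps over
#' `eps_range * median(QC)`, matching the expected 2.5-8% instrumental
#' precision; `gamma`: `n_gamma` log-spaced steps over `gamma_range`)
#' minimizing the leave-one-out cross-validation RMSE over the QC
#' injections. Ties are broken toward the smallest `gamma`, then the
#' smallest `epsilon` (smoother trend preferred). Injection order is
#' rescaled to `[0, 1]` over the batch's order range before kernel
#' evaluation so `gamma` is comparable across batch sizes.
#'
#' @param qc_intensities QC intensities (AU), strictly positive, length >= 4.
#' @param qc_orders injection orders of the QC injections.
#' @param all_orders injection orders at which the trend is evaluated
#'   (normally every injection of the batch).
#' @param eps_range epsilon search range as fractions of the QC median.
#' @param gamma_range gamma search range (per squared rescaled-order unit).
#' @param n_eps,n_gamma grid sizes.
#' @param feature_id,batch_id carried through for bookkeeping.
#' @return A `DriftFit`: list with `C`, `epsilon`, `gamma`, `rmsecv`,
#'   `trend` (predicted QC-trend intensity at each of `all_orders`),
#'   `orders`, `grid` (full grid with RMSECV per node) and ids.
#' @export
fit_qc_svrc <- function(qc_intensities, qc_orders, all_orders,
                        eps_range = c(0.025, 0.08),
                        gamma_range = c(1, 1e4),
                        n_eps = 8, n_gamma = 13,
                        feature_id = NA_character_,
                        batch_id = NA_character_) {
  n <- length(qc_intensities)
  if (n < 4) stopf("QC-SVRC needs >= 4 QC points, got %d", n)
  if (length(qc_orders) != n) stopf("qc_orders length mismatch")
  if (any(qc_intensities <= 0)) stopf("QC intensities must be positive")
  C <- stats::median(qc_intensities)
  rng <- range(c(qc_orders, all_orders))
  span <- if (diff(rng) > 0) diff(rng) else 1
  uq <- (qc_orders - rng[1]) / span
  ua <- (all_orders - rng[1]) / span

  mk_fit <- function(trend, eps = NA_real_, gamma = NA_real_,
                     rmsecv = NA_real_, grid = NULL) {
    structure(list(feature_id = feature_id, batch_id = batch_id, C = C,
                   epsilon = eps, gamma = gamma, rmsecv = rmsecv,
                   trend = trend, orders = all_orders, grid = grid),
              class = "DriftFit")
  }
  if (stats::sd(qc_intensities) < .Machine$double.eps * C) {
    # flat QC signal: constant trend = C, correction is the identity
    return(mk_fit(rep(C, length(all_orders))))
  }

  eps_vals <- seq(eps_range[1], eps_range[2], length.out = n_eps) * C
  gamma_vals <- 10^seq(log10(gamma_range[1]), log10(gamma_range[2]),
                       length.out = n_gamma)
  grid <- expand.grid(epsilon = eps_vals, gamma = gamma_vals,
                      KEEP.OUT.ATTRS = FALSE)
  # LIBSVM shuffles CV fold order; for leave-one-out the partition is fixed,
  # but we pin the RNG so the accumulation order (and hence the last few
  # digits of the RMSECV) is reproducible, and restore the caller's state.
  grid$rmsecv <- with_seed(20210717L, vapply(seq_len(nrow(grid)), function(i) {
    m <- e1071::svm(x = matrix(uq), y = qc_intensities,
                    type = "eps-regression", kernel = "radial",
                    cost = C, epsilon = grid$epsilon[i],
                    gamma = grid$gamma[i], scale = FALSE, cross = n,
                    fitted = FALSE)
    sqrt(mean(m$MSE))
  }, numeric(1)))
  best_val <- min(grid$rmsecv)
  cand <- which(grid$rmsecv <= best_val * (1 + 1e-12))
  cand <- cand[order(grid$gamma[cand], grid$epsilon[cand])]
  best <- cand[1]
  fit <- e1071::svm(x = matrix(uq), y = qc_intensities,
                    type = "eps-regression", kernel = "radial",
                    cost = C, epsilon = grid$epsilon[best],
                    gamma = grid$gamma[best], scale = FALSE, fitted = FALSE)
  trend <- svr_predict(fit, matrix(ua))
  mk_fit(trend, eps = grid$epsilon[best], gamma = grid$gamma[best],
         rmsecv = grid$rmsecv[best], grid = grid)
}

#' @export
print.DriftFit <- function(x, ...) {
  cat(sprintf(
    "QC-SVRC fit [%s / %s]: C=%.4g eps=%.4g gamma=%.4g RMSECV=%.4g\n",
    x$feature_id, x$batch_id, x$C, x$epsilon, x$gamma, x$rmsecv))
  invisible(x)
}

#' Fit QC-SVRC drift models for every feature and batch
#'
#' @param pm a `PeakMatrix` containing QC injections (role `"qc"`).
#' @param ... passed to [fit_qc_svrc()] (grid ranges and sizes).
#' @return list of `DriftFit` objects keyed `"<feature_id>|<batch_id>"`.
#' @export
fit_drift_models <- function(pm, ...) {
  batches <- unique(pm$samples$batch_id)
  fits <- list()
  for (b in batches) {
    in_b <- pm$samples$batch_id == b
    qc <- in_b & pm$samples$role == "qc"
    if (sum(qc) < 4)
      stopf("batch %s has %d QC injections; QC-SVRC needs >= 4", b, sum(qc))
    qc_ord <- pm$samples$injection_order[qc]
    all_ord <- pm$samples$injection_order[in_b]
    for (f in seq_len(ncol(pm$intensities))) {
      fid <- pm$features$feature_id[f]
      fits[[paste(fid, b, sep = "|")]] <-
        fit_qc_svrc(pm$intensities[qc, f], qc_ord, all_ord,
                    feature_id = fid, batch_id = b, ...)
    }
  }
  fits
}

#' Apply QC-SVRC drift correction
#'
#' Corrected intensity is `x * C / trend(order)`, per feature and batch:
#' the multiplicative ratio to the QC reference level, which keeps
#' intensities positive. Trend values below `floor_frac * C` are floored
#' there (with a warning) to avoid blow-ups where the fitted trend dips
#' toward zero.
#'
#' @param pm a `PeakMatrix`.
#' @param fits list from [fit_drift_models()].
#' @param floor_frac trend floor as a fraction of `C`.
#' @return Corrected `PeakMatrix` (provenance logged).
#' @export
apply_drift_correction <- function(pm, fits, floor_frac = 0.01) {
  x <- pm$intensities
  n_floored <- 0L
  for (b in unique(pm$samples$batch_id)) {
    rows <- which(pm$samples$batch_id == b)
    ords <- pm$samples$injection_order[rows]
    for (f in seq_len(ncol(x))) {
      fid <- pm$features$feature_id[f]
      fit <- fits[[paste(fid, b, sep = "|")]]
      if (is.null(fit))
        stopf("no drift fit for feature %s in batch %s", fid, b)
      tr <- fit$trend[match(ords, fit$orders)]
      if (anyNA(tr))
        stopf("drift fit for %s/%s lacks trend at some injection orders",
              fid, b)
      low <- tr < floor_frac * fit$C
      n_floored <- n_floored + sum(low)
      tr[low] <- floor_frac * fit$C
      x[rows, f] <- x[rows, f] * fit$C / tr
    }
  }
  if (n_floored > 0)
    warnf("drift trend floored at %.0f%% of C for %d point(s)",
          100 * floor_frac, n_floored)
  pm$intensities <- x
  add_provenance(pm, sprintf(
    "apply_drift_correction: QC-SVRC x*C/trend, floor %.0f%% of C (%d floored)",
    100 * floor_frac, n_floored))
}

#' One-call within-batch drift correction
#'
#' Convenience wrapper: [fit_drift_models()] then
#' [apply_drift_correction()].
#'
#' @inheritParams apply_drift_correction
#' @param ... passed to [fit_qc_svrc()].
#' @return list with the corrected `PeakMatrix` (`pm`) and the `fits`.
#' @export
correct_drift <- function(pm, floor_frac = 0.01, ...) {
  fits <- fit_drift_models(pm, ...)
  list(pm = apply_drift_correction(pm, fits, floor_frac), fits = fits)
}
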