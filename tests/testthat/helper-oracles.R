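# Independent brute-force grid oracle: explicit leave-one-out loop with a
# fresh SVR fit per held-out QC, same tie-break (smallest gamma, then
# smallest epsilon).
brute_force_svrc <- function(qc, qc_orders, all_orders,
                             eps_range = c(0.025, 0.08),
                             gamma_range = c(1, 1e4),
                             n_eps = 8, n_gamma = 13) {
  C <- median(qc)
  rng <- range(c(qc_orders, all_orders))
  u <- (qc_orders - rng[1]) / diff(rng)
  eps_vals <- seq(eps_range[1], eps_range[2], length.out = n_eps) * C
  gamma_vals <- 10^seq(log10(gamma_range[1]), log10(gamma_range[2]),
                       length.out = n_gamma)
  grid <- expand.grid(epsilon = eps_vals, gamma = gamma_vals)
  grid$rmsecv <- vapply(seq_len(nrow(grid)), function(i) {
    err <- vapply(seq_along(qc), function(j) {
      f <- e1071::svm(x = matrix(u[-j]), y = qc[-j],
                      type = "eps-regression", kernel = "radial",
                      cost = C, epsilon = grid$epsilon[i],
                      gamma = grid$gamma[i], scale = FALSE, fitted = FALSE)
      dilimet:::svr_predict(f, matrix(u[j])) - qc[j]
    }, numeric(1))
    sqrt(mean(err^2))
  }, numeric(1))
  grid
}
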