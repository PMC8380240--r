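test_that("D-ratio* matches hand-computed MAD ratios and handles edge cases", {
  # mad(qc): deviations {1,0,1,0} -> MAD 0.5; mad(study): median 11,
  # deviations {6,1,4,9,1,1} -> MAD 2.5; ratio 0.5/2.5 = 20%
  expect_equal(d_ratio_star(c(9, 10, 11, 10), c(5, 10, 15, 20, 10, 12)), 20)
  expect_equal(d_ratio_star(c(7, 7, 7), c(1, 5, 9)), 0)
  v <- c(3, 8, 1, 9, 4)
  expect_equal(d_ratio_star(v, v), 100)
  expect_identical(d_ratio_star(c(1, 2, 3), c(5, 5, 5)), Inf)
  expect_error(d_ratio_star(1, c(1, 2)), ">= 2")
})

test_that("D-ratio* filter keeps well-behaved features and removes noisy-QC ones", {
  # directly constructed: 60 features with technical CV 5% vs biological
  # CV 100%, plus 6 planted features whose QC dispersion is huge
  set.seed(17)
  n_qc <- 14; n_st <- 60; p <- 66
  planted <- 61:66
  x <- matrix(0, n_qc + n_st, p)
  for (f in 1:p) {
    qc_cv <- if (f %in% planted) 0.8 else 0.05
    x[1:n_qc, f] <- 1e5 * rlnorm(n_qc, 0, qc_cv)
    x[(n_qc + 1):(n_qc + n_st), f] <- 1e5 * rlnorm(n_st, 0, 0.8)
  }
  pm <- toy_pm(x, roles = c(rep("qc", n_qc), rep("study", n_st)))
  out <- dratio_filter(pm, max_d_ratio = 20)
  expect_true(all(sprintf("F%02d", planted) %in% out$removed))
  good_removed <- setdiff(out$removed, sprintf("F%02d", planted))
  expect_lte(length(good_removed), 0.05 * (p - length(planted)))
  expect_equal(nrow(out$metrics), p)
  # idempotent: a second pass removes nothing
  out2 <- dratio_filter(out$pm, max_d_ratio = 20)
  expect_length(out2$removed, 0)
})

test_that("between-batch scaling equalizes bridge medians exactly", {
  set.seed(5)
  p <- 6; n_b <- 5
  bridge_true <- matrix(rlnorm(n_b * p, log(1e4), 0.4), n_b, p)
  offset <- runif(p, 0.5, 2)   # batch-2 multiplicative offset per feature
  x <- rbind(bridge_true,                      # B1 bridges
             matrix(rlnorm(3 * p, log(1e4), 0.4), 3, p),  # B1 study
             sweep(bridge_true * matrix(rlnorm(n_b * p, 0, 0.05), n_b, p,
                                        byrow = TRUE) + 0, 2, offset, "*"),
             sweep(matrix(rlnorm(4 * p, log(1e4), 0.4), 4, p), 2, offset, "*"))
  roles <- c(rep("bridge", n_b), rep("study", 3),
             rep("bridge", n_b), rep("study", 4))
  batches <- c(rep("B1", n_b + 3), rep("B2", n_b + 4))
  base <- toy_pm(x, batches = batches)     # valid scaffold, all role=study
  samples <- base$samples
  samples$role <- roles
  samples$sample_id[(n_b + 4):(2 * n_b + 3)] <- samples$sample_id[1:n_b]
  samples$injection_order <- c(1:(n_b + 3), 1:(n_b + 4))
  pm <- peak_matrix(samples, base$features, x)

  out <- between_batch_scale(pm)
  # oracle: scaled per-batch bridge medians both equal the pooled median
  bridge_ids <- pm$samples$sample_id[1:n_b]
  for (f in 1:p) {
    m1 <- median(x[1:n_b, f]) / unname(out$factors[f, "B1"])
    m2 <- median(x[(n_b + 4):(2 * n_b + 3), f]) / unname(out$factors[f, "B2"])
    expect_equal(m1, m2, tolerance = 1e-12)
    pooled <- median(x[c(1:n_b, (n_b + 4):(2 * n_b + 3)), f])
    expect_equal(m1, pooled, tolerance = 1e-12)
  }
  # batch-1 replicates dropped, survivors re-labelled study
  expect_equal(nrow(out$pm$samples), nrow(pm$samples) - n_b)
  expect_false(any(out$pm$samples$role == "bridge"))
  # identical batches give unit factors
  pm_same <- pm
  pm_same$intensities[batches == "B2", ][1:n_b, ] <- x[1:n_b, ]
  out_same <- between_batch_scale(pm_same)
  expect_equal(unname(out_same$factors[, "B1"]), rep(1, p))
  expect_equal(unname(out_same$factors[, "B2"]), rep(1, p))
  expect_error(between_batch_scale(toy_pm(matrix(1:4, 2, 2))), "batches")
})

test_that("blank filter applies the 10x max-blank rule", {
  x <- rbind(study = matrix(2000, 5, 2), blank = c(100, 300))
  x[6, ] <- c(100, 300)
  pm <- toy_pm(x, roles = c(rep("study", 5), "blank"))
  out <- blank_filter(pm)
  expect_identical(out$removed, "F02")     # 3000 > 2000; 1000 <= 2000 kept
  expect_equal(ncol(out$pm$intensities), 1)
  # no blanks: warn and no-op
  pm2 <- toy_pm(matrix(1:4, 2, 2))
  expect_warning(out2 <- blank_filter(pm2), "no blank")
  expect_equal(ncol(out2$pm$intensities), 2)
  # idempotent
  out3 <- blank_filter(out$pm)
  expect_length(out3$removed, 0)
})

test_that("blank filter recovers exactly the planted contaminants", {
  st <- small_study()
  out <- blank_filter(st$peak_matrix)
  expect_setequal(out$removed, st$truth$contaminants)
})

test_that("group-intensity filter keeps features by strict group-median threshold", {
  x <- cbind(rep(14999, 6), c(rep(15001, 3), rep(100, 3)), rep(15001, 6))
  pm <- toy_pm(x, labels = rep(c("a", "b"), each = 3))
  out <- group_intensity_filter(pm, threshold = 15000)
  expect_identical(out$removed, "F01")     # all medians at 14999: removed
  expect_true(all(c("F02", "F03") %in% out$pm$features$feature_id))

  # oracle equivalence on a random matrix
  set.seed(8)
  xr <- matrix(rlnorm(40 * 25, log(15000), 1), 40, 25)
  g <- sample(c("u", "v", "w"), 40, replace = TRUE)
  pmr <- toy_pm(xr, labels = g)
  kept <- group_intensity_filter(pmr)$pm$features$feature_id
  brute <- sapply(1:25, function(f)
    max(sapply(unique(g), function(gr) median(xr[g == gr, f]))) > 15000)
  expect_identical(kept, sprintf("F%02d", which(brute)))
  # idempotent
  again <- group_intensity_filter(pmr)$pm
  expect_identical(group_intensity_filter(again)$pm$features$feature_id, kept)
})

test_that("autoscaling centers, scales, round-trips and drops constants", {
  sc <- autoscale(cbind(a = c(1, 2, 3), b = c(10, 20, 60)))
  expect_equal(unname(sc$x[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(sc$x), c(a = 0, b = 0))
  expect_equal(apply(sc$x, 2, sd), c(a = 1, b = 1))

  expect_warning(sc2 <- autoscale(cbind(a = 1:4, k = rep(7, 4))),
                 "zero-variance")
  expect_identical(sc2$dropped, "k")

  # held-out data: apply then invert recovers the original
  set.seed(2)
  train <- matrix(rnorm(30, 5, 2), 10, 3)
  test <- matrix(rnorm(15, 5, 2), 5, 3)
  sc3 <- autoscale(train)
  back <- invert_autoscale(apply_autoscale(test, sc3$center, sc3$scale),
                           sc3$center, sc3$scale)
  expect_equal(back, test, ignore_attr = TRUE)
})
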