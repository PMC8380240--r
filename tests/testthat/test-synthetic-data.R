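test_that("same design and seed give bit-identical studies", {
  a <- generate_study(small_design(seed = 9))
  b <- generate_study(small_design(seed = 9))
  expect_identical(a$peak_matrix$intensities, b$peak_matrix$intensities)
  expect_identical(a$peak_matrix$samples, b$peak_matrix$samples)
  expect_identical(a$clinical, b$clinical)
  c <- generate_study(small_design(seed = 10))
  expect_false(identical(a$peak_matrix$intensities,
                         c$peak_matrix$intensities))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); r1 <- runif(3)
  set.seed(123); invisible(generate_study(small_design(seed = 5)))
  r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("with all generators disabled every study sample equals the baseline", {
  st <- frozen_study()
  pm <- st$peak_matrix
  base <- st$truth$baseline
  stx <- pm$samples$role %in% c("study", "bridge")
  for (i in which(stx))
    expect_equal(unname(pm$intensities[i, ]), unname(base), tolerance = 1e-12)
  # QCs are the pooled mean of their batch, which here is the baseline too
  expect_equal(unname(pm$intensities[pm$samples$role == "qc", ][1, ]),
               unname(base), tolerance = 1e-12)
  # blanks sit at a small fraction of baseline except planted contaminants
  bl <- which(pm$samples$role == "blank")[1]
  ok <- !(pm$features$feature_id %in% st$truth$contaminants)
  expect_true(all(pm$intensities[bl, ok] < 0.011 * base[ok]))
  expect_true(all(pm$intensities[bl, !ok] > 0.5 * base[!ok]))
})

test_that("bridge samples share the same underlying true intensity in both batches", {
  st <- frozen_study()
  pm <- st$peak_matrix
  bridge <- unique(pm$samples$sample_id[pm$samples$role == "bridge"])
  expect_gte(length(bridge), 3)
  for (b in bridge) {
    rows <- which(pm$samples$sample_id == b)
    expect_length(rows, 2)
    expect_setequal(pm$samples$batch_id[rows], c("B1", "B2"))
    expect_equal(pm$intensities[rows[1], ], pm$intensities[rows[2], ],
                 tolerance = 1e-12)
  }
})

test_that("trajectory weights follow the geometric decay rule", {
  expect_equal(generate_trajectory("cholestatic", 4, 0.5),
               c(1, 0.5, 0.25, 0.125))
  expect_equal(generate_trajectory("hepatocellular", 3, 0),
               c(1, 1, 1))
  expect_equal(generate_trajectory("cholestatic", 2, 1), c(1, 0))
  expect_equal(generate_trajectory("recovered", 3, 0.5), c(0, 0, 0))
  expect_error(generate_trajectory("cholestatic", 0, 0.5), "n_timepoints")
  expect_error(generate_trajectory("cholestatic", 2, 1.5), "recovery_rate")
  # monotone non-increasing for any rate
  for (r in c(0, 0.2, 0.7, 1))
    expect_true(all(diff(generate_trajectory("mixed", 6, r)) <= 0))
})

test_that("degenerate designs are rejected", {
  expect_error(generate_study(small_design(n_features = 0)), "0 features")
  expect_error(generate_study(study_design(n_patients = c(cholestatic = 0,
    hepatocellular = 0, mixed = 0, recovered = 0))), "0 patients")
  expect_error(study_design(frac_bileacid_like = 0.8,
                            frac_phospholipid_like = 0.5), "fractions")
  expect_error(generate_study(small_design(), noise_cv = 1.2), "noise_cv")
})

test_that("QC injections respect the designed cadence and minimum support", {
  pm <- small_study()$peak_matrix
  for (b in c("B1", "B2"))
    expect_gte(sum(pm$samples$role == "qc" & pm$samples$batch_id == b), 4)
  # blanks are at the end of each batch
  for (b in c("B1", "B2")) {
    sb <- pm$samples[pm$samples$batch_id == b, ]
    blanks <- sb$injection_order[sb$role == "blank"]
    expect_equal(sort(blanks), seq(max(sb$injection_order) - length(blanks) + 1,
                                   max(sb$injection_order)))
  }
})

test_that("a planted strong effect is recovered by the univariate screen", {
  # two groups of 40 single-visit patients, +2 log2 effect on the
  # bile-acid-like features, moderate noise, no drift
  des <- study_design(n_patients = c(cholestatic = 40, hepatocellular = 0,
                                     mixed = 0, recovered = 40),
                      timepoints_range = c(1, 1), n_features = 120,
                      n_bridge = 4, nonrecovering_frac = 1,
                      seed = 21)
  st <- generate_study(des,
                       effects = effect_templates(
                         log2_effect_cholestatic = c(2, 0),
                         log2_effect_hepatocellular = c(0, 0)),
                       drift = drift_spec(amplitude = 0),
                       noise_cv = 0.15)
  res <- differential_features(st$peak_matrix, "cholestatic", "recovered")
  planted <- names(st$truth$feature_class)[st$truth$feature_class == "bile_acid"]
  sig <- res$feature_id[res$significant]
  recall <- mean(planted %in% sig)
  fdp <- if (length(sig)) mean(!(sig %in% planted)) else 0
  expect_gte(recall, 0.9)
  expect_lte(fdp, 0.1)
})
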