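test_that("construction validates dimensions, roles and id uniqueness", {
  x <- matrix(1:6, 3, 2)
  pm <- toy_pm(x)
  expect_s3_class(pm, "PeakMatrix")
  expect_equal(dim(pm), c(3L, 2L))

  bad_samples <- pm$samples[1:2, ]
  expect_error(peak_matrix(bad_samples, pm$features, x), "sample axis")
  expect_error(peak_matrix(pm$samples, pm$features[1, , drop = FALSE], x),
               "feature axis")

  dup <- pm$samples; dup$sample_id[2] <- dup$sample_id[1]
  expect_error(peak_matrix(dup, pm$features, x), "duplicate sample_id")

  badrole <- pm$samples; badrole$role[1] <- "calibrant"
  expect_error(peak_matrix(badrole, pm$features, x), "unknown sample role")

  dupf <- pm$features; dupf$feature_id[2] <- dupf$feature_id[1]
  expect_error(peak_matrix(pm$samples, dupf, x), "duplicate feature_id")

  neg <- x; neg[1, 1] <- -5
  expect_error(peak_matrix(pm$samples, pm$features, neg), "negative")
})

test_that("bridge samples must appear in exactly two batches", {
  x <- matrix(runif(8), 4, 2)
  expect_error(
    toy_pm(x, roles = c("bridge", "study", "study", "study"),
           batches = c("B1", "B1", "B2", "B2")),
    "bridge sample")
  # same sample_id in both batches is accepted
  samples <- toy_pm(x)$samples
  samples$role <- c("bridge", "study", "bridge", "study")
  samples$batch_id <- c("B1", "B1", "B2", "B2")
  samples$sample_id[3] <- samples$sample_id[1]
  expect_s3_class(peak_matrix(samples, toy_pm(x)$features, x), "PeakMatrix")
})

test_that("write then read round-trips a full synthetic study", {
  pm <- small_study()$peak_matrix
  pm <- dilimet:::add_provenance(pm, "unit-test entry")
  d <- withr::local_tempdir()
  paths <- write_peak_table(pm, d)
  expect_true(all(file.exists(paths)))
  pm2 <- read_peak_table(paths[["intensities"]], paths[["samples"]],
                         paths[["features"]], paths[["provenance"]])
  expect_identical(pm2$samples, pm$samples)
  expect_identical(pm2$features, pm$features)
  expect_equal(pm2$intensities, pm$intensities, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(pm2$provenance, pm$provenance)
  # provenance line count preserved
  expect_length(readLines(paths[["provenance"]]), length(pm$provenance))
})

test_that("degenerate and erroneous I/O cases", {
  # 0-sample matrix writes header-only files that read back
  pm <- toy_pm(matrix(1, 1, 2))
  pm0 <- dilimet:::pm_subset(pm, samples = integer(0))
  d <- withr::local_tempdir()
  paths <- write_peak_table(pm0, d)
  pm0b <- read_peak_table(paths[["intensities"]], paths[["samples"]],
                          paths[["features"]])
  expect_equal(dim(pm0b), c(0L, 2L))

  # metadata/matrix row mismatch on disk is a hard error naming the axis
  paths <- write_peak_table(toy_pm(matrix(1:6, 3, 2)), d)
  meta <- utils::read.delim(paths[["samples"]])
  meta <- rbind(meta, meta[3, ]); meta$sample_id[4] <- "S99"
  utils::write.table(meta, paths[["samples"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_peak_table(paths[["intensities"]], paths[["samples"]],
                               paths[["features"]]), "sample axis")
  expect_error(read_peak_table("nope.tsv", paths[["samples"]],
                               paths[["features"]]), "not found")
  expect_error(write_peak_table(pm, "/proc/definitely/unwritable"),
               "cannot write")
})

test_that("empty intensity cells become missing values and are dropped before modelling", {
  d <- withr::local_tempdir()
  pm <- toy_pm(matrix(as.numeric(1:12), 4, 3))
  paths <- write_peak_table(pm, d)
  lines <- readLines(paths[["intensities"]])
  lines[2] <- sub("^(\\S+\t)\\S+", "\\1", lines[2])  # blank one cell
  writeLines(lines, paths[["intensities"]])
  pm2 <- read_peak_table(paths[["intensities"]], paths[["samples"]],
                         paths[["features"]])
  expect_equal(sum(is.na(pm2$intensities)), 1L)
  expect_match(tail(pm2$provenance, 1), "missing")
  pm3 <- dilimet:::drop_missing_features(pm2)
  expect_equal(ncol(pm3$intensities), 2L)
})

test_that("combine_modes concatenates and split_modes inverts it", {
  pm_all <- small_study()$peak_matrix
  pm_all <- dilimet:::pm_subset(pm_all,
                                samples = which(pm_all$samples$role == "study"))
  pos <- dilimet:::pm_subset(pm_all, features = 1:5)
  neg0 <- dilimet:::pm_subset(pm_all, features = 6:12)
  neg <- dilimet:::pm_subset(neg0, samples = sample(nrow(neg0$samples)))
  comb <- combine_modes(pos, neg)
  expect_equal(ncol(comb$intensities),
               ncol(pos$intensities) + ncol(neg$intensities))
  expect_identical(comb$samples$sample_id, pos$samples$sample_id)

  back <- split_modes(comb)
  expect_equal(back$pos$intensities, pos$intensities, ignore_attr = TRUE)
  expect_identical(back$pos$features$feature_id, pos$features$feature_id)
  expect_equal(ncol(back$neg$intensities), ncol(neg$intensities))

  # asymmetric sample sets are rejected, naming the odd one out
  neg_cut <- dilimet:::pm_subset(neg, samples = -1)
  expect_error(combine_modes(pos, neg_cut),
               neg$samples$sample_id[1], fixed = TRUE)
})

test_that("provenance log is append-only and grows by one per transformation", {
  st <- small_study()
  pm <- st$peak_matrix
  n0 <- length(pm$provenance)
  out <- blank_filter(pm)
  expect_length(out$pm$provenance, n0 + 1)
  expect_identical(out$pm$provenance[seq_len(n0)], pm$provenance)
  out2 <- group_intensity_filter(out$pm, groups = rep("g",
    sum(out$pm$samples$role %in% c("study", "bridge"))))
  expect_length(out2$pm$provenance, n0 + 2)
})
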