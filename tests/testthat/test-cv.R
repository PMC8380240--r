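test_that("subjectwise folds never split a patient and are reproducible", {
  pid <- rep(sprintf("P%02d", 1:12), times = sample(1:4, 12, replace = TRUE))
  s1 <- subjectwise_folds(pid, k = 4, seed = 2)
  s2 <- subjectwise_folds(pid, k = 4, seed = 2)
  expect_identical(s1$fold, s2$fold)
  for (p in unique(pid))
    expect_length(unique(s1$fold[pid == p]), 1)
  s3 <- subjectwise_folds(pid, k = 4, seed = 3)
  expect_false(identical(s1$fold, s3$fold))
  expect_error(subjectwise_folds(pid, k = 13, seed = 1), "exceeds")
  expect_error(subjectwise_folds(pid, k = 1, seed = 1), ">= 2")
})

test_that("one sample per patient reduces to stratified sample-wise CV", {
  pid <- sprintf("P%02d", 1:20)
  y <- rep(c(0, 1), 10)
  s <- subjectwise_folds(pid, k = 5, seed = 1, labels = y)
  expect_equal(as.integer(table(s$fold)), rep(4L, 5))
  # stratification keeps both classes in every training split
  for (f in 1:5)
    expect_setequal(unique(y[s$fold != f]), c(0, 1))
})

test_that("LV selection finds a planted two-dimensional signal", {
  # class fully separable only in the plane of two X directions: the first
  # weight vector is pulled off the separating normal by a high-variance
  # nuisance direction, so one LV misclassifies and two suffice
  set.seed(11)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  e1 <- rnorm(n, 0, 1.2)
  X <- cbind(y + e1, y - 0.9 * e1 + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 4), n, 4))
  pid <- sprintf("P%03d", seq_len(n))
  sch <- subjectwise_folds(pid, k = 4, seed = 5, labels = y)
  expect_equal(select_n_lv(X, y, sch, max_lv = 5), 2)
  expect_equal(select_n_lv(X, y, sch, max_lv = 1), 1)
})

test_that("double CV covers every sample once with no patient leakage", {
  set.seed(12)
  pid <- rep(sprintf("P%02d", 1:20), each = 3)
  n <- length(pid)
  X <- matrix(rnorm(n * 15), n, 15)
  y <- as.numeric(rep(rbinom(20, 1, 0.5), each = 3))
  y[1:3] <- 1; y[4:6] <- 0   # both classes guaranteed
  dcv <- double_cv(X, y, pid, k_outer = 4, k_inner = 3, max_lv = 4, seed = 9)
  expect_length(dcv$y_hat, n)
  expect_false(anyNA(dcv$y_hat))
  # leakage check: each sample's fold model excluded its whole patient
  for (f in seq_len(dcv$scheme$k)) {
    test_pats <- unique(pid[dcv$scheme$fold == f])
    train_pats <- unique(pid[dcv$scheme$fold != f])
    expect_length(intersect(test_pats, train_pats), 0)
  }
})

test_that("double CV separates separable classes and not permuted ones", {
  set.seed(13)
  n_pat <- 24
  pid <- rep(sprintf("P%02d", 1:n_pat), each = 2)
  y <- rep(rep(c(0, 1), n_pat / 2), each = 2)
  X <- matrix(rnorm(length(pid) * 30), length(pid), 30)
  X[, 1:5] <- X[, 1:5] + 3 * y     # strong planted effect
  dcv <- double_cv(X, y, pid, k_outer = 4, k_inner = 3, seed = 1)
  expect_gte(auroc(y, dcv$y_hat), 0.9)

  null_aucs <- sapply(1:5, function(i) {
    yp <- rep(sample(rep(c(0, 1), n_pat / 2)), each = 2)
    dcv0 <- double_cv(X, yp, pid, k_outer = 4, k_inner = 3, seed = i)
    auroc(yp, dcv0$y_hat)
  })
  expect_lt(abs(mean(null_aucs) - 0.5), 0.15)
})

test_that("AUROC equals brute-force pair counting and pROC", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_equal(auroc(c(1, 0), c(5, 1)), 1)
  expect_equal(auroc(c(1, 1, 0), c(2, 2, 2)), 0.5)
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "both classes")

  pair_count <- function(lab, sc) {   # independent oracle
    pos <- which(lab == 1); neg <- which(lab == 0)
    tot <- 0
    for (i in pos) for (j in neg)
      tot <- tot + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
    tot / (length(pos) * length(neg))
  }
  set.seed(14)
  for (i in 1:25) {
    lab <- c(0, 1, rbinom(sample(5:20, 1), 1, 0.5))
    sc <- round(rnorm(length(lab)), 1)   # rounded: ties occur
    expect_equal(auroc(lab, sc), pair_count(lab, sc))
    expect_equal(auroc(lab, sc),
                 suppressMessages(as.numeric(pROC::auc(
                   pROC::roc(lab, sc, quiet = TRUE, direction = "<")))))
    # invariant under strictly monotone transforms
    expect_equal(auroc(lab, sc), auroc(lab, exp(2 * sc)))
  }
})

test_that("permutation p attains its add-one lower bound on separable data", {
  set.seed(15)
  pid <- rep(sprintf("P%02d", 1:16), each = 2)
  y <- rep(rep(c(0, 1), 8), each = 2)
  X <- matrix(rnorm(32 * 10), 32, 10)
  X[, 1:3] <- X[, 1:3] + 4 * y
  pt <- permutation_test(X, y, pid, n_perm = 24, k_outer = 4, k_inner = 3,
                         seed = 4)
  expect_equal(pt$p, 1 / 25)
  expect_length(pt$perm_auroc, 24)
  expect_error(permutation_test(X, y, pid, n_perm = 5), ">= 20")
})

test_that("the one-vs-rest suite trains three models and holds mixed aside", {
  st <- small_study()
  cd <- small_corrected()
  pm <- cd$pm
  ovr <- one_vs_rest_suite(pm, n_perm = 0, k_outer = 3, k_inner = 3,
                           max_lv = 4, seed = 2)
  expect_named(ovr$auroc, c("cholestatic", "hepatocellular", "recovered"))
  expect_true(all(ovr$auroc >= 0 & ovr$auroc <= 1))
  expect_gt(ovr$auroc[["cholestatic"]], 0.7)
  # mixed samples were predicted by the full models, never cross-validated
  expect_true(all(ovr$predictions$source[ovr$predictions$label == "mixed"]
                  == "full"))
  expect_true(all(ovr$predictions$source[ovr$predictions$label != "mixed"]
                  == "2cv"))
  expect_equal(mean(vip(ovr$models$cholestatic)^2), 1, tolerance = 1e-12)
  # removing one class is an error
  pm2 <- pm
  drop <- pm2$samples$phenotype_label == "hepatocellular"
  pm2$samples$phenotype_label[drop] <- "recovered"
  expect_error(one_vs_rest_suite(pm2), "hepatocellular")
})
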