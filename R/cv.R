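#' Subjectwise cross-validation folds
#'
#' Patients, not samples, are randomized to folds, so repeated samples of
#' one patient never straddle train and test. When labels are supplied the
#' assignment is stratified on the patient-level majority label, and folds
#' are re-drawn (up to 100 times) until every class is present in every
#' training split.
#'
#' @param patient_ids character vector, one entry per sample.
#' @param k number of folds, at most the number of distinct patients.
#' @param seed integer seed (same seed, same folds).
#' @param labels optional per-sample class labels used for stratification.
#' @return list of class `cv_scheme`: `fold` (integer per sample),
#'   `patient_fold` (named integer per patient), `k`, `seed`.
#' @export
subjectwise_folds <- function(patient_ids, k, seed = 1L, labels = NULL) {
  pts <- unique(patient_ids)
  if (k < 2) stopf("k must be >= 2")
  if (k > length(pts))
    stopf("k = %d exceeds the number of distinct patients (%d)",
          k, length(pts))
  pt_label <- if (is.null(labels)) rep("all", length(pts)) else
    vapply(pts, function(p) {
      tab <- table(labels[patient_ids == p])
      names(tab)[which.max(tab)]   # majority, first level on ties
    }, character(1))
  draw <- function(attempt) with_seed(child_seed(seed, "folds", attempt), {
    pf <- integer(length(pts)); names(pf) <- pts
    offset <- 0L
    for (g in unique(pt_label)) {
      idx <- sample(which(pt_label == g))
      pf[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)   # rotate start to balance fold sizes
    }
    pf
  })
  for (attempt in 0:100) {
    pf <- draw(attempt)
    fold <- unname(pf[patient_ids])
    if (is.null(labels)) break
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(labels[fold != f])) == length(unique(labels)), TRUE))
    if (ok) break
    if (attempt == 100)
      stopf("could not build folds with every class in every training split")
  }
  structure(list(fold = fold, patient_fold = pf, k = k, seed = seed),
            class = "cv_scheme")
}

#' Select the number of latent variables by CV classification accuracy
#'
#' For each fold a model with the maximal feasible LV count is fit on the
#' training split and its per-LV predictions pooled over held-out samples;
#' the returned LV count maximizes the pooled classification accuracy
#' (decision threshold 0.5 on the 0/1 coding), ties broken toward the
#' fewest LVs.
#'
#' @param X raw feature matrix (scaling is refit per training split inside
#'   [fit_pls()]).
#' @param y 0/1 response vector.
#' @param scheme a `cv_scheme` over the same samples.
#' @param max_lv largest LV count considered.
#' @return integer LV count.
#' @export
select_n_lv <- function(X, y, scheme, max_lv = 10) {
  if (max_lv < 1) stopf("max_lv must be >= 1")
  n <- length(y)
  a_cap <- max_lv
  yhat <- matrix(NA_real_, n, max_lv)
  for (f in seq_len(scheme$k)) {
    tr <- scheme$fold != f
    if (all(tr) || !any(tr)) next
    a_max <- min(max_lv, sum(tr) - 1, ncol(X))
    m <- fit_pls(X[tr, , drop = FALSE], y[tr], a_max)
    ph <- predict_pls_all(m, X[!tr, , drop = FALSE])
    a_fit <- ncol(ph)
    a_cap <- min(a_cap, a_fit)
    yhat[!tr, seq_len(a_fit)] <- ph
    if (a_fit < max_lv)   # pad with the deepest available prediction
      yhat[!tr, (a_fit + 1):max_lv] <- ph[, a_fit]
  }
  acc <- vapply(seq_len(a_cap), function(a)
    mean((yhat[, a] >= 0.5) == (y >= 0.5), na.rm = TRUE), numeric(1))
  which.max(acc)   # first maximum = fewest LVs
}

#' Double (nested) cross-validation predictions
#'
#' Outer subjectwise folds are held out in turn; on the remaining data an
#' inner subjectwise CV selects the LV count, a model with that count is
#' fit on all non-test data, and the held-out fold is predicted. Every
#' sample receives exactly one out-of-sample prediction, and by
#' construction no model ever saw its predicted sample's patient.
#'
#' @param X raw feature matrix.
#' @param y 0/1 response per sample.
#' @param patient_ids patient id per sample.
#' @param k_outer,k_inner outer/inner fold counts.
#' @param max_lv largest LV count considered by the inner loop.
#' @param seed integer seed.
#' @return list: `y_hat` (out-of-sample prediction per sample), `n_lv`
#'   (selected count per outer fold), `scheme` (outer `cv_scheme`).
#' @export
double_cv <- function(X, y, patient_ids, k_outer = 7, k_inner = 5,
                      max_lv = 10, seed = 1L) {
  X <- as.matrix(X)
  outer <- subjectwise_folds(patient_ids, k_outer, seed, labels = y)
  y_hat <- rep(NA_real_, length(y))
  n_lv <- integer(k_outer)
  for (f in seq_len(k_outer)) {
    tr <- outer$fold != f
    inner <- subjectwise_folds(patient_ids[tr],
                               min(k_inner, length(unique(patient_ids[tr]))),
                               child_seed(seed, "inner", f), labels = y[tr])
    a <- select_n_lv(X[tr, , drop = FALSE], y[tr], inner, max_lv)
    m <- fit_pls(X[tr, , drop = FALSE], y[tr], a)
    y_hat[!tr] <- predict(m, X[!tr, , drop = FALSE])
    n_lv[f] <- m$n_lv
  }
  stopifnot(!anyNA(y_hat))   # coverage: each sample predicted exactly once
  list(y_hat = y_hat, n_lv = n_lv, scheme = outer)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half; invariant under strictly monotone transforms of the
#' scores.
#'
#' @param labels binary labels (0/1 or logical).
#' @param scores continuous scores.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  pos <- labels == 1 | labels == TRUE
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("auroc needs both classes present")
  r <- rank(scores)   # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Permutation test of a 2CV AUROC
#'
#' Class labels are permuted at the patient level (each patient's majority
#' label is reassigned to another patient and inherited by all of that
#' patient's samples, preserving the repeated-measures structure), the full
#' double-CV pipeline is re-run per permutation, and
#' `p = (1 + #{perm AUROC >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams double_cv
#' @param n_perm number of permutations (>= 20).
#' @param observed optional pre-computed observed AUROC (skips one 2CV run).
#' @return list: `p`, `observed`, `perm_auroc` (vector of permuted AUROCs).
#' @export
permutation_test <- function(X, y, patient_ids, n_perm = 100,
                             k_outer = 7, k_inner = 5, max_lv = 10,
                             seed = 1L, observed = NULL) {
  if (n_perm < 20) stopf("n_perm must be >= 20")
  if (is.null(observed)) {
    obs_cv <- double_cv(X, y, patient_ids, k_outer, k_inner, max_lv, seed)
    observed <- auroc(y, obs_cv$y_hat)
  }
  pts <- unique(patient_ids)
  pt_label <- vapply(pts, function(p) {
    tab <- table(y[patient_ids == p])
    as.numeric(names(tab)[which.max(tab)])
  }, numeric(1))
  perm_auroc <- vapply(seq_len(n_perm), function(b) {
    y_b <- with_seed(child_seed(seed, "perm", b), {
      repeat {
        pl <- sample(pt_label)
        y_try <- unname(pl[match(patient_ids, pts)])
        if (length(unique(y_try)) > 1) break
      }
      y_try
    })
    cv_b <- double_cv(X, y_b, patient_ids, k_outer, k_inner, max_lv,
                      child_seed(seed, "perm", b))
    auroc(y_b, cv_b$y_hat)
  }, numeric(1))
  list(p = (1 + sum(perm_auroc >= observed)) / (n_perm + 1),
       observed = observed, perm_auroc = perm_auroc)
}

#' One-vs-rest PLS-DA suite over the three DILI phenotypes
#'
#' Decomposes the three-class problem (cholestatic, hepatocellular,
#' recovered) into three binary one-vs-rest models. Mixed-type samples are
#' held aside from all training. Each model reports subjectwise double-CV
#' out-of-sample predictions (and AUROC, optionally with a patient-level
#' permutation p) for the training samples; a full model, with its LV count
#' selected by subjectwise CV on all training data, supplies VIP scores and
#' the predictions for the held-aside mixed samples. A final 2-LV PLS2
#' model on the union of the three VIP > 1 feature sets is fit for the
#' score/loading overview.
#'
#' @param pm filtered `PeakMatrix` of study samples (raw intensities;
#'   autoscaling is refit inside every training split).
#' @param n_perm permutations for the AUROC test; 0 skips it.
#' @param k_outer,k_inner,max_lv CV control, see [double_cv()].
#' @param vip_threshold VIP cut for the discriminant feature sets.
#' @param seed integer seed.
#' @return list of class `ovr_result`: `predictions` (per sample: the three
#'   constrained-to-be-continuous y's and their provenance 2cv/full),
#'   `auroc`, `perm_p`, `n_lv`, `vip` (features x models), `vip_sets`,
#'   `vip_intersections`, `models`, `pls2` (final 2-LV PLS2 model),
#'   `pls2_features`.
#' @export
one_vs_rest_suite <- function(pm, n_perm = 0, k_outer = 7, k_inner = 5,
                              max_lv = 10, vip_threshold = 1, seed = 1L) {
  st <- pm$samples$role %in% c("study", "bridge")
  lab <- pm$samples$phenotype_label[st]
  sample_id <- pm$samples$sample_id[st]
  patient_id <- pm$samples$patient_id[st]
  X <- pm$intensities[st, , drop = FALSE]
  classes <- c("cholestatic", "hepatocellular", "recovered")
  missing <- setdiff(classes, unique(lab))
  if (length(missing))
    stopf("class(es) absent from the study samples: %s",
          paste(missing, collapse = ", "))
  train <- lab %in% classes
  mixed <- !train
  Xt <- X[train, , drop = FALSE]

  models <- list(); cv_pred <- list(); aucs <- numeric(); pp <- list()
  vip_mat <- matrix(NA_real_, ncol(X), length(classes),
                    dimnames = list(pm$features$feature_id[], classes))
  n_lv_used <- integer(length(classes)); names(n_lv_used) <- classes
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    yv <- as.numeric(lab[train] == cl)
    dcv <- double_cv(Xt, yv, patient_id[train], k_outer, k_inner, max_lv,
                     child_seed(seed, "folds", ci))
    cv_pred[[cl]] <- dcv$y_hat
    aucs[cl] <- auroc(yv, dcv$y_hat)
    if (n_perm > 0)
      pp[[cl]] <- permutation_test(Xt, yv, patient_id[train], n_perm,
                                   k_outer, k_inner, max_lv,
                                   child_seed(seed, "perm", ci),
                                   observed = aucs[cl])
    sel_scheme <- subjectwise_folds(patient_id[train],
                                    min(k_inner,
                                        length(unique(patient_id[train]))),
                                    child_seed(seed, "inner", 100L + ci),
                                    labels = yv)
    a <- select_n_lv(Xt, yv, sel_scheme, max_lv)
    m <- fit_pls(Xt, yv, a)
    models[[cl]] <- m
    n_lv_used[cl] <- m$n_lv
    vip_mat[, cl] <- vip(m)
  }

  pred <- matrix(NA_real_, nrow(X), length(classes),
                 dimnames = list(sample_id, classes))
  for (cl in classes) {
    pred[train, cl] <- cv_pred[[cl]]
    if (any(mixed))
      pred[mixed, cl] <- predict(models[[cl]], X[mixed, , drop = FALSE])
  }
  predictions <- data.frame(sample_id = sample_id,
                            patient_id = patient_id,
                            label = lab,
                            y_cholestatic = pred[, "cholestatic"],
                            y_hepatocellular = pred[, "hepatocellular"],
                            y_recovered = pred[, "recovered"],
                            source = ifelse(train, "2cv", "full"),
                            row.names = NULL)

  vip_sets <- lapply(classes, function(cl)
    rownames(vip_mat)[vip_mat[, cl] > vip_threshold])
  names(vip_sets) <- classes
  union_feats <- unique(unlist(vip_sets))
  pls2 <- NULL
  if (length(union_feats) >= 2) {
    Y3 <- vapply(classes, function(cl) as.numeric(lab[train] == cl),
                 numeric(sum(train)))
    pls2 <- fit_pls(Xt[, union_feats, drop = FALSE], Y3,
                    n_lv = min(2, length(union_feats), sum(train) - 1))
  }
  structure(list(predictions = predictions,
                 auroc = aucs,
                 perm_p = if (n_perm > 0)
                   vapply(pp, `[[`, 0, "p") else NULL,
                 perm_detail = if (n_perm > 0) pp else NULL,
                 n_lv = n_lv_used,
                 vip = vip_mat,
                 vip_sets = vip_sets,
                 vip_intersections = if (length(unlist(vip_sets)))
                   intersect_counts(vip_sets) else NULL,
                 models = models,
                 pls2 = pls2,
                 pls2_features = union_feats),
            class = "ovr_result")
}

#' @export
print.ovr_result <- function(x, ...) {
  cat("One-vs-rest PLS-DA suite\n")
  for (cl in names(x$auroc))
    cat(sprintf("  %-15s 2CV AUROC %.3f%s  (%d LV, %d features VIP>1)\n",
                cl, x$auroc[[cl]],
                if (!is.null(x$perm_p))
                  sprintf(", perm p %.3f", x$perm_p[[cl]]) else "",
                x$n_lv[[cl]], length(x$vip_sets[[cl]])))
  invisible(x)
}
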