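#' Robust dispersion ratio D-ratio*
#'
#' `100 * robust_sd(QC) / robust_sd(study)` with
#' `robust_sd = 1.4826 * median absolute deviation` (the starred, robust
#' variant of the QC dispersion ratio). Features whose technical (QC)
#' variability is large relative to the biological (study-sample)
#' variability are uninformative and are removed at 20% in the default
#' pipeline.
#'
#' @param qc_values QC intensities after drift correction (>= 2 values).
#' @param study_values study-sample intensities (>= 2 values).
#' @return percentage; `Inf` when the study dispersion is zero.
#' @export
d_ratio_star <- function(qc_values, study_values) {
  if (length(qc_values) < 2 || length(study_values) < 2)
    stopf("d_ratio_star needs >= 2 values in each vector")
  s_qc <- stats::mad(qc_values)      # 1.4826 * MAD
  s_st <- stats::mad(study_values)
  if (s_st == 0) return(Inf)
  100 * s_qc / s_st
}

#' D-ratio* quality filter
#'
#' Computes per-feature QC relative standard deviation and D-ratio* and
#' removes features with `D-ratio* > max_d_ratio` (or infinite D-ratio*).
#' The filter runs after within-batch correction but before between-batch
#' scaling, so dispersions are computed within each batch (its QCs against
#' its study samples) and the worst batch decides; pooling QCs across
#' batches would confound the technical dispersion with the between-batch
#' offset that bridge scaling removes later.
#'
#' @param pm drift-corrected `PeakMatrix`.
#' @param max_d_ratio removal threshold, percent.
#' @return list: `pm` (filtered), `metrics` (feature_id, rsd_qc,
#'   d_ratio_star; worst batch per feature), `removed` (feature ids).
#' @export
dratio_filter <- function(pm, max_d_ratio = 20) {
  if (sum(pm$samples$role == "qc") < 2)
    stopf("D-ratio* filter needs >= 2 QC injections")
  per_batch <- lapply(unique(pm$samples$batch_id), function(b) {
    qc <- pm$samples$role == "qc" & pm$samples$batch_id == b
    st <- pm$samples$role %in% c("study", "bridge") &
      pm$samples$batch_id == b
    if (sum(qc) < 2 || sum(st) < 2) return(NULL)
    list(dr = vapply(seq_len(ncol(pm$intensities)), function(f)
           d_ratio_star(pm$intensities[qc, f], pm$intensities[st, f]),
           numeric(1)),
         rsd = vapply(seq_len(ncol(pm$intensities)), function(f) {
           v <- pm$intensities[qc, f]
           100 * stats::sd(v) / mean(v)
         }, numeric(1)))
  })
  per_batch <- Filter(Negate(is.null), per_batch)
  if (!length(per_batch)) stopf("no batch with >= 2 QCs and >= 2 study samples")
  dr <- do.call(pmax, lapply(per_batch, `[[`, "dr"))
  rsd <- do.call(pmax, lapply(per_batch, `[[`, "rsd"))
  metrics <- data.frame(feature_id = pm$features$feature_id,
                        rsd_qc = rsd, d_ratio_star = dr)
  keep <- is.finite(dr) & dr <= max_d_ratio
  removed <- pm$features$feature_id[!keep]
  out <- pm_subset(pm, features = which(keep))
  out <- add_provenance(out, sprintf(
    "dratio_filter: removed %d/%d features with D-ratio* > %g%%",
    sum(!keep), length(keep), max_d_ratio))
  list(pm = out, metrics = metrics, removed = removed)
}

#' Between-batch scaling on bridge samples
#'
#' For each feature and batch `b`, the scaling factor is
#' `median(bridge intensities in b) / median(bridge intensities pooled
#' across batches)`; all intensities of batch `b` are divided by it. This
#' equalizes the per-feature bridge medians across batches exactly.
#' Afterwards the batch-1 copies of the bridge samples are dropped and the
#' surviving batch-2 copies re-labelled as study samples. Features whose
#' pooled bridge median is zero cannot be scaled and are excluded.
#'
#' @param pm `PeakMatrix` with bridge samples in two batches.
#' @param bridge_ids bridge sample ids; defaults to all role `"bridge"`.
#' @return list: `pm` (scaled, bridge duplicates dropped), `factors`
#'   (features x batches matrix), `excluded` (unscalable feature ids).
#' @export
between_batch_scale <- function(pm, bridge_ids = NULL) {
  s <- pm$samples
  bridge_ids <- bridge_ids %||% unique(s$sample_id[s$role == "bridge"])
  batches <- unique(s$batch_id)
  if (length(batches) < 2) stopf("between-batch scaling needs >= 2 batches")
  rows_b <- lapply(batches, function(b)
    which(s$batch_id == b & s$sample_id %in% bridge_ids))
  names(rows_b) <- batches
  if (any(vapply(rows_b, length, 1L) < 3))
    stopf("need >= 3 bridge samples present in every batch")
  pool_rows <- unlist(rows_b)
  x <- pm$intensities
  med_pool <- apply(x[pool_rows, , drop = FALSE], 2, stats::median)
  factors <- vapply(batches, function(b)
    apply(x[rows_b[[b]], , drop = FALSE], 2, stats::median) / med_pool,
    numeric(ncol(x)))
  excluded <- pm$features$feature_id[med_pool == 0]
  for (b in batches)
    x[s$batch_id == b, ] <- sweep(x[s$batch_id == b, , drop = FALSE], 2,
                                  factors[, b], "/")
  pm$intensities <- x
  keep_f <- med_pool > 0
  pm <- pm_subset(pm, features = which(keep_f))
  factors <- factors[keep_f, , drop = FALSE]
  # drop the batch-1 replicate of each bridge sample, keep the batch-2 copy
  drop_rows <- which(s$batch_id == batches[1] & s$sample_id %in% bridge_ids)
  pm <- pm_subset(pm, samples = setdiff(seq_len(nrow(pm$samples)), drop_rows))
  pm$samples$role[pm$samples$role == "bridge"] <- "study"
  pm <- add_provenance(pm, sprintf(
    "between_batch_scale: %d bridge samples, %d feature(s) unscalable, batch-1 replicates dropped",
    length(bridge_ids), sum(!keep_f)))
  list(pm = pm, factors = factors, excluded = excluded)
}

#' Blank contamination filter
#'
#' Removes a feature iff `blank_factor * max(blank intensities)` exceeds
#' the median intensity over study samples. With no blanks present the
#' matrix is returned unchanged with a warning.
#'
#' @param pm `PeakMatrix`.
#' @param blank_factor multiplier on the maximum blank signal.
#' @return list: `pm` (filtered) and `removed` (feature ids).
#' @export
blank_filter <- function(pm, blank_factor = 10) {
  bl <- pm$samples$role == "blank"
  st <- pm$samples$role %in% c("study", "bridge")
  if (!any(bl)) {
    warnf("no blank injections present; blank filter skipped")
    return(list(pm = pm, removed = character()))
  }
  bmax <- apply(pm$intensities[bl, , drop = FALSE], 2, max)
  smed <- apply(pm$intensities[st, , drop = FALSE], 2, stats::median)
  keep <- !(blank_factor * bmax > smed)
  removed <- pm$features$feature_id[!keep]
  out <- pm_subset(pm, features = which(keep))
  out <- add_provenance(out, sprintf(
    "blank_filter: removed %d feature(s) with %gx max(blank) > median(study)",
    sum(!keep), blank_factor))
  list(pm = out, removed = removed)
}

#' Group-median intensity filter
#'
#' Keeps a feature iff the within-group median intensity exceeds
#' `threshold` (strictly) in at least one phenotype group. Empty groups are
#' ignored with a warning.
#'
#' @param pm `PeakMatrix`.
#' @param groups phenotype label per study sample; defaults to the
#'   `phenotype_label` column of the study samples.
#' @param threshold intensity threshold (AU).
#' @return list: `pm` (filtered) and `removed` (feature ids).
#' @export
group_intensity_filter <- function(pm, groups = NULL, threshold = 15000) {
  st <- which(pm$samples$role %in% c("study", "bridge"))
  groups <- groups %||% pm$samples$phenotype_label[st]
  if (length(groups) != length(st))
    stopf("need one group label per study sample (%d vs %d)",
          length(groups), length(st))
  if (anyNA(groups)) stopf("every study sample must be labelled")
  keep_mat <- vapply(unique(groups), function(g) {
    rows <- st[groups == g]
    if (length(rows) == 0) {
      warnf("empty group '%s' ignored", g)
      return(rep(FALSE, ncol(pm$intensities)))
    }
    apply(pm$intensities[rows, , drop = FALSE], 2, stats::median) > threshold
  }, logical(ncol(pm$intensities)))
  keep <- apply(keep_mat, 1, any)
  removed <- pm$features$feature_id[!keep]
  out <- pm_subset(pm, features = which(keep))
  out <- add_provenance(out, sprintf(
    "group_intensity_filter: removed %d feature(s) with all group medians <= %g AU",
    sum(!keep), threshold))
  list(pm = out, removed = removed)
}

# Drop features flagged as drug metabolites or food components.
excluded_flag_filter <- function(pm) {
  keep <- pm$features$excluded_flag %in% c("none", "", NA)
  out <- pm_subset(pm, features = which(keep))
  add_provenance(out, sprintf(
    "excluded_flag_filter: removed %d flagged feature(s)", sum(!keep)))
}

#' Autoscale a study-sample matrix
#'
#' Centers each feature to mean 0 and scales to sample standard deviation 1
#' (unit variance). Zero-variance features cannot be scaled and are dropped
#' with a warning.
#'
#' @param x numeric matrix, samples x features.
#' @return list: `x` (scaled matrix), `center`, `scale` (named vectors over
#'   retained features), `dropped` (names of zero-variance features).
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("autoscaling needs >= 2 samples")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- scl < .Machine$double.eps^0.5
  if (any(zero))
    warnf("autoscale: dropped %d zero-variance feature(s)", sum(zero))
  x <- x[, !zero, drop = FALSE]
  ctr <- ctr[!zero]; scl <- scl[!zero]
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  list(x = xs, center = ctr, scale = scl,
       dropped = names(zero)[zero] %||% character())
}

#' Apply stored autoscaling constants to new data
#' @param x matrix over the same features as the stored constants.
#' @param center,scale constants from [autoscale()].
#' @return scaled matrix.
#' @export
apply_autoscale <- function(x, center, scale) {
  sweep(sweep(as.matrix(x), 2, center), 2, scale, "/")
}

#' Invert autoscaling
#' @inheritParams apply_autoscale
#' @return matrix on the original scale.
#' @export
invert_autoscale <- function(x, center, scale) {
  sweep(sweep(as.matrix(x), 2, scale, "*"), 2, center, "+")
}
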