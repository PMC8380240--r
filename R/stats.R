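#' Welch two-sample t-test
#'
#' Two-sided test of equal means with unknown, unequal variances
#' (Welch-Satterthwaite degrees of freedom). Thin wrapper over
#' [stats::t.test()] that additionally defines the degenerate cases
#' `t.test` refuses: two constant groups with equal values give
#' `t = 0, p = 1`; constant groups with different values give an infinite
#' statistic and `p = 0`.
#'
#' @param x,y numeric vectors, >= 2 observations each.
#' @return list with `t`, `dof`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stopf("welch_t needs >= 2 observations per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, dof = Inf, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, dof = Inf, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), dof = unname(tt$parameter),
       p = tt$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1, original
#' order restored (delegates to [stats::p.adjust()]).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted vector of the same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-feature differential screening between two phenotype groups
#'
#' Welch t per feature, BH-FDR across all tested features within this one
#' comparison (not pooled across comparisons), significance at
#' `p_adj < alpha`.
#'
#' @param pm `PeakMatrix`.
#' @param group_a,group_b phenotype labels to compare.
#' @param alpha FDR significance level.
#' @return data frame: feature_id, t_stat, dof, p, p_adj, significant.
#' @export
differential_features <- function(pm, group_a, group_b, alpha = 0.05) {
  st <- pm$samples$role %in% c("study", "bridge")
  lab <- pm$samples$phenotype_label
  ia <- which(st & lab == group_a)
  ib <- which(st & lab == group_b)
  if (length(ia) == 0) stopf("no study samples in group '%s'", group_a)
  if (length(ib) == 0) stopf("no study samples in group '%s'", group_b)
  res <- lapply(seq_len(ncol(pm$intensities)), function(f)
    welch_t(pm$intensities[ia, f], pm$intensities[ib, f]))
  out <- data.frame(feature_id = pm$features$feature_id,
                    t_stat = vapply(res, `[[`, 0, "t"),
                    dof = vapply(res, `[[`, 0, "dof"),
                    p = vapply(res, `[[`, 0, "p"))
  out$p_adj <- bh_fdr(out$p)
  out$significant <- out$p_adj < alpha
  out
}

#' Exclusive intersection counts of named feature sets
#'
#' UpSet semantics: each feature is counted in exactly one cell, the cell
#' of the combination of sets it belongs to. Cell counts therefore sum to
#' the size of the union.
#'
#' @param sets named list of character vectors (>= 2 sets).
#' @return data frame: `cell` (set names joined by `&`), `count`.
#' @export
intersect_counts <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)))
    stopf("intersect_counts needs >= 2 named sets")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  cell <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  tab <- table(cell)
  data.frame(cell = names(tab), count = as.integer(tab),
             row.names = NULL)
}

#' PCA overview of an autoscaled matrix
#'
#' Singular-value decomposition of the (already centered/scaled) matrix via
#' [stats::prcomp()]; reports scores, loadings and the percentage of
#' variance explained per component.
#'
#' @param x autoscaled matrix, samples x features.
#' @param k number of components to return; truncated to the matrix rank
#'   with a warning when too large.
#' @return list: `scores` (n x k), `loadings` (p x k), `explained_var`
#'   (percent per component).
#' @export
pca_overview <- function(x, k = 4) {
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  avail <- sum(pc$sdev > .Machine$double.eps^0.5 * pc$sdev[1])
  if (k > avail) {
    warnf("requested %d components but rank is %d; truncated", k, avail)
    k <- avail
  }
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_var = ev[seq_len(k)])
}
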