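#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with the study's
#' defaults: D-ratio* cut 20%, blank factor 10, group-median intensity
#' threshold 15000 AU, epsilon search range 2.5-8% of the QC median, gamma
#' range `[1, 1e4]`, FDR level 0.05, VIP cut 1, subjectwise 7-fold outer /
#' 5-fold inner double CV, 100 permutations, ALT/ALP upper normal limits
#' 56 and 147 U/L.
#'
#' @param d_ratio_max,blank_factor,intensity_threshold quality-filter
#'   thresholds.
#' @param eps_range,gamma_range,n_eps,n_gamma QC-SVRC grid, see
#'   [fit_qc_svrc()].
#' @param trend_floor_frac drift-trend floor, fraction of C.
#' @param alpha FDR significance level for the univariate screen.
#' @param vip_threshold VIP cut for discriminant features.
#' @param k_outer,k_inner,max_lv,n_perm PLS-DA CV control.
#' @param alt_unl,alp_unl clinical upper normal limits (U/L).
#' @param seed master seed; fans out to per-stage child seeds.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(d_ratio_max = 20, blank_factor = 10,
                            intensity_threshold = 15000,
                            eps_range = c(0.025, 0.08),
                            gamma_range = c(1, 1e4),
                            n_eps = 8, n_gamma = 13,
                            trend_floor_frac = 0.01,
                            alpha = 0.05, vip_threshold = 1,
                            k_outer = 7, k_inner = 5, max_lv = 10,
                            n_perm = 100,
                            alt_unl = 56, alp_unl = 147,
                            seed = 1L) {
  cfg <- as.list(environment())
  num <- c("d_ratio_max", "blank_factor", "intensity_threshold", "alpha",
           "vip_threshold", "alt_unl", "alp_unl")
  if (any(unlist(cfg[num]) <= 0)) stopf("thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

#' Run the full DILI phenotyping pipeline
#'
#' Executes, per ESI mode: within-batch QC-SVRC drift correction, D-ratio*
#' filter, between-batch bridge scaling and blank filter; then (on the
#' combined matrix) the drug-metabolite/food-component exclusion flag,
#' clinical R-scores and rule-based phenotype labels, the group-median
#' intensity filter, PCA overview, Welch/BH univariate screening of the
#' three pairwise comparisons, the one-vs-rest PLS-DA suite with
#' subjectwise double CV, and the ternary mapping with per-patient
#' trajectories. Every intermediate table is written under `out_dir`
#' together with a machine-readable JSON manifest and a plain-text log; a
#' fixed `seed` in the config makes the whole run deterministic.
#'
#' @param peak a `PeakMatrix`, or a list with elements `pos` and `neg` for
#'   the two ESI modes.
#' @param clinical clinical table with `sample_id`, `alt`, `alp` (plus
#'   `patient_id`, `timepoint` for trajectories).
#' @param config a [pipeline_config()].
#' @param out_dir output directory; `NULL` skips file output.
#' @return list with every stage result (invisibly when writing files).
#' @export
run_all <- function(peak, clinical, config = pipeline_config(),
                    out_dir = NULL) {
  log_lines <- character()
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message(msg)
  }
  stage <- "input validation"
  res <- tryCatch({
    modes <- if (inherits(peak, "PeakMatrix")) list(combined = peak)
             else peak[c("pos", "neg")]
    metrics <- list(); fits <- list()
    for (mn in names(modes)) {
      pm <- modes[[mn]]
      stage <- paste("QC-SVRC drift correction,", mn)
      note("[%s] QC-SVRC grid search on %d features x %d batches", mn,
           ncol(pm$intensities), length(unique(pm$samples$batch_id)))
      cd <- correct_drift(pm, floor_frac = config$trend_floor_frac,
                          eps_range = config$eps_range,
                          gamma_range = config$gamma_range,
                          n_eps = config$n_eps, n_gamma = config$n_gamma)
      pm <- cd$pm; fits[[mn]] <- cd$fits
      stage <- paste("D-ratio* filter,", mn)
      dr <- dratio_filter(pm, config$d_ratio_max)
      pm <- dr$pm; metrics[[mn]] <- dr$metrics
      note("[%s] D-ratio* filter removed %d feature(s)", mn,
           length(dr$removed))
      if (length(unique(pm$samples$batch_id)) > 1 &&
          any(pm$samples$role == "bridge")) {
        stage <- paste("between-batch scaling,", mn)
        pm <- between_batch_scale(pm)$pm
        note("[%s] between-batch bridge scaling applied", mn)
      }
      stage <- paste("blank filter,", mn)
      bf <- blank_filter(pm, config$blank_factor)
      pm <- bf$pm
      note("[%s] blank filter removed %d feature(s)", mn, length(bf$removed))
      modes[[mn]] <- pm
    }
    stage <- "mode combination"
    pm <- if (length(modes) == 1) modes[[1]]
          else combine_modes(modes$pos, modes$neg)
    pm <- excluded_flag_filter(pm)
    pm <- drop_missing_features(pm)

    stage <- "clinical scoring"
    clin <- add_clinical_scores(clinical, config$alt_unl, config$alp_unl)
    st <- pm$samples$role %in% c("study", "bridge")
    idx <- match(pm$samples$sample_id[st], clin$sample_id)
    if (anyNA(idx))
      stopf("clinical table lacks sample(s): %s",
            paste(utils::head(pm$samples$sample_id[st][is.na(idx)], 5),
                  collapse = ", "))
    pm$samples$phenotype_label[st] <- clin$phenotype_label[idx]
    note("clinical labels: %s",
         paste(sprintf("%s=%d", names(table(clin$phenotype_label)),
                       table(clin$phenotype_label)), collapse = " "))

    stage <- "group-intensity filter"
    gi <- group_intensity_filter(pm, threshold = config$intensity_threshold)
    pm <- gi$pm
    note("group-intensity filter kept %d feature(s)", ncol(pm$intensities))

    stage <- "PCA overview"
    Xs <- autoscale(pm$intensities[st, , drop = FALSE])
    pca <- pca_overview(Xs$x, k = min(4, ncol(Xs$x), sum(st) - 1))
    note("PCA: first %d PCs explain %.2f%% of the variance",
         length(pca$explained_var), sum(pca$explained_var))

    stage <- "univariate screening"
    comparisons <- list(c("cholestatic", "hepatocellular"),
                        c("cholestatic", "recovered"),
                        c("hepatocellular", "recovered"))
    screens <- lapply(comparisons, function(cp)
      differential_features(pm, cp[1], cp[2], config$alpha))
    names(screens) <- vapply(comparisons, paste, "", collapse = "_vs_")
    sig_sets <- lapply(screens, function(s) s$feature_id[s$significant])
    note("significant features: %s",
         paste(sprintf("%s=%d", names(sig_sets), lengths(sig_sets)),
               collapse = " "))

    stage <- "one-vs-rest PLS-DA"
    ovr <- one_vs_rest_suite(pm, n_perm = config$n_perm,
                             k_outer = config$k_outer,
                             k_inner = config$k_inner,
                             max_lv = config$max_lv,
                             vip_threshold = config$vip_threshold,
                             seed = child_seed(config$seed, "pipeline"))
    note("2CV AUROC: %s",
         paste(sprintf("%s=%.3f", names(ovr$auroc), ovr$auroc),
               collapse = " "))

    stage <- "ternary mapping"
    tern <- to_ternary(ovr$predictions$y_cholestatic,
                       ovr$predictions$y_hepatocellular,
                       ovr$predictions$y_recovered)
    coords <- cbind(ovr$predictions[, c("sample_id", "patient_id", "label")],
                    tern)
    coords$timepoint <-
      pm$samples$timepoint_index[st][match(coords$sample_id,
                                           pm$samples$sample_id[st])]
    traj <- build_trajectories(coords)
    note("ternary coordinates for %d samples, %d patients",
         nrow(traj), length(unique(traj$patient_id)))

    list(peak_matrix = pm, clinical = clin, qc_metrics = metrics,
         drift_fits = fits, pca = pca, screens = screens,
         significant_sets = sig_sets, ovr = ovr, trajectories = traj,
         log = log_lines)
  }, error = function(e) {
    stopf("pipeline aborted at stage '%s': %s\n  provenance so far:\n  %s",
          stage, conditionMessage(e), paste(log_lines, collapse = "\n  "))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_peak_table(res$peak_matrix, file.path(out_dir, "peak_matrix"))
    write_tsv(res$clinical, file.path(out_dir, "clinical_scored.tsv"))
    for (mn in names(res$qc_metrics))
      write_tsv(res$qc_metrics[[mn]],
                file.path(out_dir, sprintf("qc_metrics_%s.tsv", mn)))
    for (sn in names(res$screens))
      write_tsv(res$screens[[sn]],
                file.path(out_dir, sprintf("screen_%s.tsv", sn)))
    write_tsv(data.frame(pc = seq_along(res$pca$explained_var),
                         explained_var = res$pca$explained_var),
              file.path(out_dir, "pca_explained_variance.tsv"))
    write_tsv(data.frame(res$pca$scores), file.path(out_dir, "pca_scores.tsv"))
    write_tsv(res$ovr$predictions, file.path(out_dir, "ovr_predictions.tsv"))
    write_tsv(data.frame(feature_id = rownames(res$ovr$vip), res$ovr$vip),
              file.path(out_dir, "vip_scores.tsv"))
    write_tsv(res$trajectories, file.path(out_dir, "ternary_coordinates.tsv"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("dilimet")),
      r_version = R.version.string,
      config = unclass(config),
      n_samples = nrow(res$peak_matrix$intensities),
      n_features = ncol(res$peak_matrix$intensities),
      auroc = as.list(res$ovr$auroc),
      perm_p = as.list(res$ovr$perm_p %||% list()))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(res$log, file.path(out_dir, "run.log"))
    return(invisible(res))
  }
  res
}

#' Generate a synthetic study and write it to disk
#'
#' Wraps [generate_study()] and writes the peak table plus the clinical
#' table as TSV, ready for [run_all()] (quickstart: `simulate_study()` then
#' `run_all()` on the written files).
#'
#' @param design a [study_design()].
#' @param out_dir output directory.
#' @param ... passed to [generate_study()].
#' @return list: `paths` (written files) and the generated `study`,
#'   invisibly.
#' @export
simulate_study <- function(design = study_design(), out_dir, ...) {
  study <- generate_study(design, ...)
  paths <- write_peak_table(study$peak_matrix, out_dir)
  clin_path <- file.path(out_dir, "clinical.tsv")
  write_tsv(study$clinical, clin_path)
  invisible(list(paths = c(paths, clinical = clin_path), study = study))
}
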