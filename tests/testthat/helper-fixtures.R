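# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small but complete two-batch study, cheap enough for unit tests
small_design <- function(seed = 7, ...) {
  args <- list(n_patients = c(cholestatic = 6, hepatocellular = 5,
                              mixed = 3, recovered = 6),
               timepoints_range = c(1, 3), n_features = 40, n_bridge = 4,
               batch1_qc_interval = 4, batch2_qc_interval = 5,
               seed = seed)
  do.call(study_design, utils::modifyList(args, list(...)))
}

small_study <- function() memo("small_study", generate_study(small_design()))

small_corrected <- function() memo("small_corrected", {
  correct_drift(small_study()$peak_matrix, n_eps = 3, n_gamma = 5)
})

# a noiseless, drift-free, effect-free study: every study intensity equals
# the feature baseline exactly
frozen_study <- function() memo("frozen_study", {
  des <- small_design(seed = 3, biological_cv = 0, batch_effect_sd = 0)
  generate_study(des,
                 effects = effect_templates(log2_effect_cholestatic = c(0, 0),
                                            log2_effect_hepatocellular = c(0, 0)),
                 drift = drift_spec(amplitude = 0),
                 noise_cv = 0)
})

# hand-built tiny PeakMatrix for targeted filter tests
toy_pm <- function(x, roles = NULL, batches = NULL, labels = NULL,
                   orders = NULL) {
  n <- nrow(x); p <- ncol(x)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    patient_id = sprintf("P%02d", seq_len(n)),
    injection_order = orders %||% seq_len(n),
    batch_id = batches %||% rep("B1", n),
    role = roles %||% rep("study", n),
    phenotype_label = labels %||% rep("unknown", n),
    timepoint_index = 1L)
  samples$patient_id[samples$role %in% c("qc", "blank")] <- ""
  features <- data.frame(
    feature_id = sprintf("F%02d", seq_len(p)),
    mz = 100 + seq_len(p), rt = 60 + seq_len(p),
    esi_mode = "positive", annotation = "", metabolite_class = "",
    metabolite_subclass = "", excluded_flag = "none")
  peak_matrix(samples, features, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
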