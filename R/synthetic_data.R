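#' Study design for the synthetic data generator
#'
#' The defaults emulate the structure of a two-batch untargeted LC-MS DILI
#' study: four phenotype groups with longitudinal sampling, pooled QC
#' injections every 8 samples in batch 1 and every 10 in batch 2, 15 bridge
#' samples re-injected in batch 2 for between-batch scaling, and blanks at
#' the end of each batch (2 and 6). Baseline intensities are drawn
#' log-uniformly over `baseline_range` (default 1e4 to 1e6 AU) so the
#' 15000 AU group-intensity filter is exercised on both sides of its
#' threshold.
#'
#' @param n_patients named integer vector: patients per phenotype
#'   (`cholestatic`, `hepatocellular`, `mixed`, `recovered`).
#' @param timepoints_range inclusive range of samples per patient.
#' @param n_features number of LC-MS features.
#' @param frac_bileacid_like,frac_phospholipid_like fractions of features
#'   carrying the bile-acid-like and glycerophospholipid-like effect
#'   templates; must sum to at most 1.
#' @param batch1_qc_interval,batch2_qc_interval study injections between
#'   consecutive QC injections.
#' @param n_bridge number of batch-1 study samples re-injected in batch 2.
#' @param n_blanks length-2 integer: blanks at the end of batches 1 and 2.
#' @param n_contaminants features given a high blank signal (planted
#'   contaminants for the blank filter).
#' @param baseline_range range of baseline feature intensities (AU).
#' @param biological_cv between-sample biological coefficient of variation
#'   (log-normal, per sample and feature). Serum metabolite levels vary far
#'   more between subjects than the instrument's technical noise; this is
#'   also what the D-ratio* filter divides by.
#' @param batch_effect_sd log-normal sd of the per-feature batch-2
#'   multiplier (the between-batch effect bridge scaling must remove).
#' @param recovery_rate geometric per-timepoint decay of the DILI effect for
#'   recovering patients (0 = no recovery).
#' @param nonrecovering_frac fraction of multi-timepoint DILI patients whose
#'   effect does not decay (rate 0).
#' @param alt_unl,alp_unl upper normal limits used when planting clinical
#'   chemistry.
#' @param seed integer seed; identical designs generate identical studies.
#' @return A `study_design` list.
#' @export
study_design <- function(n_patients = c(cholestatic = 18, hepatocellular = 14,
                                        mixed = 8, recovered = 20),
                         timepoints_range = c(1, 5),
                         n_features = 300,
                         frac_bileacid_like = 0.15,
                         frac_phospholipid_like = 0.15,
                         batch1_qc_interval = 8,
                         batch2_qc_interval = 10,
                         n_bridge = 15,
                         n_blanks = c(2, 6),
                         n_contaminants = 5,
                         baseline_range = c(1e4, 1e6),
                         biological_cv = 0.6,
                         batch_effect_sd = 0.15,
                         recovery_rate = 0.4,
                         nonrecovering_frac = 0.15,
                         alt_unl = 56, alp_unl = 147,
                         seed = 1L) {
  if (frac_bileacid_like < 0 || frac_phospholipid_like < 0 ||
      frac_bileacid_like + frac_phospholipid_like > 1)
    stopf("feature-class fractions must be in [0,1] and sum to at most 1")
  if (any(n_patients < 0) || n_features < 0)
    stopf("counts must be non-negative")
  structure(as.list(environment()), class = "study_design")
}

#' Phenotype effect templates
#'
#' Multiplicative log2 effects versus the recovered baseline (recovered is
#' exactly 0 on the log scale). Defaults encode the qualitative biology the
#' analysis targets: conjugated bile acids strongly elevated in cholestatic
#' injury (and mildly in hepatocellular), glycerophosphocholines /
#' -ethanolamines decreased in active DILI of either type. The magnitudes
#' are free parameters of the simulator, not estimates from patients.
#'
#' @param feature_class,log2_effect_cholestatic,log2_effect_hepatocellular
#'   parallel vectors defining one template per feature class.
#' @return data frame of effect templates.
#' @export
effect_templates <- function(feature_class = c("bile_acid", "phospholipid"),
                             log2_effect_cholestatic = c(2, -1),
                             log2_effect_hepatocellular = c(0.5, -1.5)) {
  data.frame(feature_class = feature_class,
             log2_effect_cholestatic = log2_effect_cholestatic,
             log2_effect_hepatocellular = log2_effect_hepatocellular)
}

#' Within-batch drift specification
#'
#' `amplitude` is the maximum relative deviation of the drift multiplier
#' from 1 (clamped so the multiplier stays strictly positive);
#' `per_feature_variation` spreads per-feature amplitudes uniformly within
#' `amplitude * (1 +/- per_feature_variation)`. The default `smooth-random`
#' family builds each feature's trend from a random cubic polynomial of
#' injection order, deliberately a different functional form than the RBF
#' support-vector corrector so the correction test is not self-fulfilling.
#'
#' @param family drift family.
#' @param amplitude maximum relative deviation from unity.
#' @param per_feature_variation relative spread of per-feature amplitudes.
#' @return A `drift_spec` list.
#' @export
drift_spec <- function(family = c("smooth-random", "linear",
                                  "exponential-decay"),
                       amplitude = 0.3, per_feature_variation = 0.5) {
  family <- match.arg(family)
  if (amplitude < 0) stopf("amplitude must be non-negative")
  structure(list(family = family, amplitude = amplitude,
                 per_feature_variation = per_feature_variation),
            class = "drift_spec")
}

#' Per-timepoint DILI effect weights of a longitudinal patient
#'
#' Geometric decay toward the recovered baseline: weight at timepoint `t`
#' is `(1 - recovery_rate)^(t - 1)`, so rate 0 gives a constant
#' (non-recovering) profile and rate 1 full recovery at the second visit.
#' A weight of 0 means the recovered baseline; recovered-phenotype patients
#' have weight 0 throughout.
#'
#' @param phenotype patient phenotype label.
#' @param n_timepoints number of visits (>= 1).
#' @param recovery_rate per-step decay fraction in `[0, 1]`.
#' @return Numeric vector of monotonically non-increasing weights in
#'   `[0, 1]`.
#' @export
generate_trajectory <- function(phenotype, n_timepoints, recovery_rate) {
  if (n_timepoints < 1) stopf("n_timepoints must be >= 1")
  if (recovery_rate < 0 || recovery_rate > 1)
    stopf("recovery_rate must be in [0, 1]")
  if (phenotype == "recovered") return(rep(0, n_timepoints))
  (1 - recovery_rate)^(seq_len(n_timepoints) - 1)
}

# log-normal multiplicative noise with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# truncated log-normal via inverse CDF
rlnorm_trunc <- function(n, meanlog, sdlog, lo = 0, hi = Inf) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

# drift multiplier curve over rescaled injection order u in [0,1]
drift_curve <- function(family, u, amp) {
  g <- switch(family,
    "smooth-random" = {
      # random cubic of injection order, centered to mean 0 over the batch:
      # a constant multiplier is a batch-level offset (handled separately by
      # the batch-effect term), not within-batch drift, so only the
      # variation over injection order counts toward the amplitude
      a <- stats::rnorm(4)
      v <- a[1] + a[2] * u + a[3] * u^2 + a[4] * u^3
      v <- v - mean(v)
      m <- max(abs(v))
      if (m < .Machine$double.eps) rep(0, length(u)) else v / m
    },
    "linear" = sample(c(-1, 1), 1) * (2 * u - 1),
    "exponential-decay" = {
      s <- sample(c(-1, 1), 1)
      s * (2 * (exp(-3 * u) - exp(-3)) / (1 - exp(-3)) - 1)
    })
  1 + min(amp, 0.95) * g
}

# clinical chemistry consistent with a planted per-sample label; draws are
# anchored on the group means of the study's clinical table and truncated so
# the rule-based classifier reproduces the planted label.
plant_clinical <- function(labels, alt_unl, alp_unl) {
  n <- length(labels)
  alt <- alp <- numeric(n)
  k <- alt_unl / alp_unl  # ALT = R * ALP * k
  for (lab in unique(labels)) {
    i <- which(labels == lab)
    m <- length(i)
    if (lab == "cholestatic") {
      r <- rlnorm_trunc(m, log(0.8), 0.35, 0.05, 1.9)
      alp[i] <- rlnorm_trunc(m, log(341), 0.30, alp_unl + 3, Inf)
      alt[i] <- r * alp[i] * k
    } else if (lab == "hepatocellular") {
      r <- rlnorm_trunc(m, log(15), 0.50, 5.2, 80)
      alp[i] <- rlnorm_trunc(m, log(128), 0.30, 40, Inf)
      alt[i] <- r * alp[i] * k
    } else if (lab == "mixed") {
      r <- stats::runif(m, 2.2, 4.8)
      alp[i] <- rlnorm_trunc(m, log(138), 0.30, 70, Inf)
      alt[i] <- r * alp[i] * k
    } else { # recovered
      alt[i] <- rlnorm_trunc(m, log(28), 0.30, 1, alt_unl - 1)
      alp[i] <- rlnorm_trunc(m, log(87), 0.30, 10, alp_unl - 1)
    }
  }
  anchors <- list(
    cholestatic    = c(ast = 74, ggt = 472, bili = 7,   alb = 3.9),
    mixed          = c(ast = 82, ggt = 189, bili = 2,   alb = 4.1),
    hepatocellular = c(ast = 482, ggt = 249, bili = 8,  alb = 3.9),
    recovered      = c(ast = 29, ggt = 61,  bili = 0.7, alb = 4.3))
  ast <- ggt <- bili <- alb <- numeric(n)
  for (lab in unique(labels)) {
    i <- which(labels == lab); m <- length(i); a <- anchors[[lab]]
    ast[i] <- stats::rlnorm(m, log(a[["ast"]]), 0.4)
    ggt[i] <- stats::rlnorm(m, log(a[["ggt"]]), 0.5)
    bili[i] <- stats::rlnorm(m, log(a[["bili"]]), 0.5)
    alb[i] <- pmax(2, stats::rnorm(m, a[["alb"]], 0.3))
  }
  data.frame(alt = alt, alp = alp, ast = ast, ggt = ggt,
             total_bilirubin = bili, albumin = alb)
}

#' Generate a complete synthetic DILI metabolomics study
#'
#' Produces a `PeakMatrix` with two acquisition batches (QC injections at the
#' designed intervals, bridge samples re-injected in batch 2, blanks at batch
#' end) plus a matching clinical table. The intensity of feature `f` in
#' sample `s` is
#' `baseline_f * 2^(w_s * effect_f) * bio_sf * batch_mult_f * drift_f(order_s) * noise`,
#' where `w_s` is the patient's recovery weight at that timepoint,
#' `effect_f` the phenotype effect (mixed patients receive a per-patient
#' convex blend, weight uniform on 0.3-0.7, of the cholestatic and
#' hepatocellular effect vectors), `bio_sf` log-normal between-sample
#' biological variation (CV `biological_cv`), `batch_mult_f` a per-feature
#' batch-2 multiplier, drift the within-batch multiplicative trend and noise
#' log-normal with CV `noise_cv`. QC injections carry the pooled mean of the
#' batch's study intensities under the same drift and noise; blanks carry
#' 0.2-1% of baseline except for `n_contaminants` planted contaminant
#' features with blank signal near the baseline level. Bridge samples share
#' the same underlying true intensity in both batches (only drift, batch
#' multiplier and noise differ).
#'
#' Per-sample planted labels follow the trajectory: a DILI patient's sample
#' is labelled with the patient phenotype while its effect weight is at
#' least 0.5 and `recovered` below that; clinical chemistry is drawn
#' conditional on the planted label (see [plant_clinical] internals) so the
#' rule-based classifier reproduces the planted labels.
#'
#' @param design a [study_design()].
#' @param effects an [effect_templates()] data frame.
#' @param drift a [drift_spec()].
#' @param noise_cv multiplicative noise coefficient of variation, in (0, 1).
#' @return list with `peak_matrix`, `clinical` (one row per unique study
#'   sample: sample_id, patient_id, timepoint, alt, alp, ast, ggt,
#'   total_bilirubin, albumin, label) and `truth` (planted effect vectors,
#'   per-sample weights, contaminant and per-class feature ids).
#' @export
generate_study <- function(design = study_design(),
                           effects = effect_templates(),
                           drift = drift_spec(),
                           noise_cv = 0.1) {
  stopifnot(inherits(design, "study_design"))
  if (noise_cv < 0 || noise_cv >= 1) stopf("noise_cv must be in [0, 1)")
  if (design$n_features < 1) stopf("degenerate design: 0 features")
  if (sum(design$n_patients) < 1) stopf("degenerate design: 0 patients")
  with_seed(design$seed, generate_study_impl(design, effects, drift, noise_cv))
}

generate_study_impl <- function(design, effects, drift, noise_cv) {
  d <- design
  nf <- d$n_features

  ## -- features ------------------------------------------------------------
  n_ba <- round(d$frac_bileacid_like * nf)
  n_pl <- round(d$frac_phospholipid_like * nf)
  fclass <- c(rep("bile_acid", n_ba), rep("phospholipid", n_pl),
              rep("other", nf - n_ba - n_pl))
  subclass_of <- c(bile_acid = "Bile acids, alcohols and derivatives",
                   phospholipid = "Glycerophosphocholines", other = "")
  class_of <- c(bile_acid = "Steroids and steroid derivatives",
                phospholipid = "Glycerophospholipids", other = "")
  features <- data.frame(
    feature_id = sprintf("F%04d", seq_len(nf)),
    mz = round(stats::runif(nf, 70, 1200), 4),
    rt = round(stats::runif(nf, 30, 540), 1),
    esi_mode = rep_len(c("positive", "negative"), nf),
    annotation = ifelse(fclass == "other", "", paste0("met_", seq_len(nf))),
    metabolite_class = unname(class_of[fclass]),
    metabolite_subclass = unname(subclass_of[fclass]),
    excluded_flag = "none")
  baseline <- exp(stats::runif(nf, log(d$baseline_range[1]),
                               log(d$baseline_range[2])))
  other_idx <- which(fclass == "other")
  contam <- sort(sample(other_idx, min(d$n_contaminants, length(other_idx))))

  e_chol <- e_hep <- numeric(nf)
  for (i in seq_len(nrow(effects))) {
    sel <- fclass == effects$feature_class[i]
    e_chol[sel] <- effects$log2_effect_cholestatic[i]
    e_hep[sel] <- effects$log2_effect_hepatocellular[i]
  }

  ## -- patients and study samples ------------------------------------------
  pheno <- rep(names(d$n_patients), d$n_patients)
  n_pat <- length(pheno)
  patients <- data.frame(patient_id = sprintf("P%03d", seq_len(n_pat)),
                         phenotype = pheno,
                         stringsAsFactors = FALSE)
  patients$n_tp <- sample(seq(d$timepoints_range[1], d$timepoints_range[2]),
                          n_pat, replace = TRUE)
  patients$rate <- ifelse(
    patients$phenotype == "recovered", 0,
    ifelse(stats::runif(n_pat) < d$nonrecovering_frac, 0, d$recovery_rate))
  patients$blend <- ifelse(patients$phenotype == "mixed",
                           stats::runif(n_pat, 0.3, 0.7), NA_real_)

  samp <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
    p <- patients[i, ]
    w <- generate_trajectory(p$phenotype, p$n_tp, p$rate)
    data.frame(patient_id = p$patient_id, phenotype = p$phenotype,
               timepoint_index = seq_len(p$n_tp), weight = w)
  }))
  samp$sample_id <- sprintf("S%04d", seq_len(nrow(samp)))
  ns <- nrow(samp)

  # planted per-sample label: phenotype while effect weight >= 0.5
  samp$label <- ifelse(samp$phenotype != "recovered" & samp$weight >= 0.5,
                       samp$phenotype, "recovered")

  # per-sample log2 effect vectors (features x samples)
  eff <- vapply(seq_len(ns), function(j) {
    p <- patients[match(samp$patient_id[j], patients$patient_id), ]
    base_eff <- switch(p$phenotype,
      cholestatic = e_chol, hepatocellular = e_hep,
      mixed = p$blend * e_chol + (1 - p$blend) * e_hep,
      recovered = numeric(nf))
    samp$weight[j] * base_eff
  }, numeric(nf))
  # per-sample biological variation on top of the phenotype effect; part of
  # the "true" intensity, so bridge re-injections share it across batches
  bio <- matrix(rlnorm_cv(nf * ns, d$biological_cv), nf, ns)
  true_int <- baseline * 2^eff * bio      # features x samples

  ## -- batch layout ---------------------------------------------------------
  ord <- sample.int(ns)
  n_b1 <- ceiling(ns / 2)
  b1_samples <- sort(ord[seq_len(n_b1)])
  b2_samples <- sort(ord[-seq_len(n_b1)])
  bridge_idx <- sort(sample(b1_samples, min(d$n_bridge, length(b1_samples))))

  build_batch <- function(study_idx, bridge_in_batch, qc_interval, n_blank,
                          batch_id, qc_prefix) {
    inj <- list()
    push <- function(type, idx = NA_integer_) inj[[length(inj) + 1L]] <<-
      list(type = type, idx = idx)
    payload <- c(study_idx, bridge_in_batch)  # sample rows injected here
    payload <- sample(payload)                # injection order randomized
    push("qc")
    for (i in seq_along(payload)) {
      push(if (payload[i] %in% bridge_in_batch && batch_id == "B2")
        "bridge" else "study", payload[i])
      if (i %% qc_interval == 0) push("qc")
    }
    if (inj[[length(inj)]]$type != "qc") push("qc")
    # QC-SVRC needs >= 4 QC supports per batch
    while (sum(vapply(inj, function(e) e$type == "qc", TRUE)) < 4) push("qc")
    for (b in seq_len(n_blank)) push("blank")
    types <- vapply(inj, `[[`, "", "type")
    idxs <- vapply(inj, `[[`, 0L, "idx")
    qc_n <- cumsum(types == "qc")
    blank_n <- cumsum(types == "blank")
    data.frame(
      batch_id = batch_id,
      injection_order = seq_along(types),
      type = types,
      sample_row = idxs,
      sample_id = ifelse(types == "qc", sprintf("%s_%02d", qc_prefix, qc_n),
                  ifelse(types == "blank",
                         sprintf("BLK%s_%02d", sub("B", "", batch_id), blank_n),
                         samp$sample_id[idxs])))
  }
  lay1 <- build_batch(b1_samples, integer(0), d$batch1_qc_interval,
                      d$n_blanks[1], "B1", "QC1")
  lay2 <- build_batch(b2_samples, bridge_idx, d$batch2_qc_interval,
                      d$n_blanks[2], "B2", "QC2")
  # in batch 1 the bridge rows are flagged bridge as well (they appear twice)
  lay1$type[lay1$sample_row %in% bridge_idx & lay1$type == "study"] <- "bridge"
  layout <- rbind(lay1, lay2)

  ## -- intensities ----------------------------------------------------------
  batch_mult <- cbind(B1 = rep(1, nf),
                      B2 = exp(stats::rnorm(nf, 0, d$batch_effect_sd)))
  blank_base <- baseline * stats::runif(nf, 0.002, 0.01)
  blank_base[contam] <- baseline[contam] * stats::runif(length(contam), 0.6, 1.2)

  X <- matrix(NA_real_, nrow(layout), nf,
              dimnames = list(NULL, features$feature_id))
  for (b in c("B1", "B2")) {
    rows <- which(layout$batch_id == b)
    n_inj <- length(rows)
    u <- (layout$injection_order[rows] - 1) / max(1, n_inj - 1)
    amp <- pmax(0, drift$amplitude * (1 + drift$per_feature_variation *
                                        stats::runif(nf, -1, 1)))
    pool_rows <- layout$sample_row[rows][layout$type[rows] %in%
                                           c("study", "bridge")]
    qc_base <- rowMeans(true_int[, pool_rows, drop = FALSE])
    for (f in seq_len(nf)) {
      dcurve <- drift_curve(drift$family, u, amp[f])
      base <- numeric(n_inj)
      ty <- layout$type[rows]
      base[ty %in% c("study", "bridge")] <-
        true_int[f, layout$sample_row[rows][ty %in% c("study", "bridge")]]
      base[ty == "qc"] <- qc_base[f]
      base[ty == "blank"] <- blank_base[f]
      X[rows, f] <- base * batch_mult[f, b] * dcurve *
        rlnorm_cv(n_inj, noise_cv)
    }
  }

  ## -- assemble -------------------------------------------------------------
  srow <- layout$sample_row
  samples <- data.frame(
    sample_id = layout$sample_id,
    patient_id = ifelse(layout$type %in% c("study", "bridge"),
                        samp$patient_id[srow], ""),
    injection_order = layout$injection_order,
    batch_id = layout$batch_id,
    role = ifelse(layout$type == "bridge", "bridge", layout$type),
    timepoint_index = ifelse(layout$type %in% c("study", "bridge"),
                             samp$timepoint_index[srow], NA_integer_),
    phenotype_label = ifelse(layout$type %in% c("study", "bridge"),
                             samp$label[srow], "unknown"))
  pm <- peak_matrix(samples, features, X,
                    provenance = sprintf(
                      "generate_study: seed=%d, %d patients, %d features, drift=%s amp=%.2f, noise_cv=%.2f",
                      d$seed, n_pat, nf, drift$family, drift$amplitude,
                      noise_cv))

  clin_lab <- plant_clinical(samp$label, d$alt_unl, d$alp_unl)
  clinical <- data.frame(sample_id = samp$sample_id,
                         patient_id = samp$patient_id,
                         timepoint = samp$timepoint_index,
                         round(clin_lab, 2),
                         label = samp$label)

  truth <- list(baseline = stats::setNames(baseline, features$feature_id),
                effect_cholestatic = stats::setNames(e_chol, features$feature_id),
                effect_hepatocellular = stats::setNames(e_hep, features$feature_id),
                feature_class = stats::setNames(fclass, features$feature_id),
                contaminants = features$feature_id[contam],
                patients = patients,
                sample_weights = stats::setNames(samp$weight, samp$sample_id),
                true_intensity = t(true_int))

  list(peak_matrix = pm, clinical = clinical, truth = truth)
}
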