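#' Peak matrix: samples x features intensity table with metadata
#'
#' The single data currency of the pipeline. `samples` is a data frame with
#' one row per injection (columns `sample_id`, `patient_id`,
#' `injection_order`, `batch_id`, `role`, `timepoint_index`,
#' `phenotype_label`), `features` one row per LC-MS feature (columns
#' `feature_id`, `mz`, `rt`, `esi_mode`, `annotation`, `metabolite_class`,
#' `metabolite_subclass`, `excluded_flag`), and `intensities` a numeric
#' matrix (arbitrary units) with `nrow(samples)` rows and `nrow(features)`
#' columns. `provenance` is an append-only character log of the
#' transformations applied so far.
#'
#' Bridge samples (role `"bridge"`) are study samples re-injected in a second
#' acquisition batch; they share their `sample_id` across the two batches,
#' so sample ids are only required to be unique *within* a batch.
#'
#' @param samples sample metadata data frame (see Details).
#' @param features feature metadata data frame (see Details).
#' @param intensities numeric matrix, samples x features, non-negative
#'   (missing values allowed until modelling).
#' @param provenance character vector of transformation descriptions.
#' @return An object of class `PeakMatrix`.
#' @export
peak_matrix <- function(samples, features, intensities,
                        provenance = character()) {
  pm <- structure(
    list(samples = as.data.frame(samples),
         features = as.data.frame(features),
         intensities = as.matrix(intensities),
         provenance = as.character(provenance)),
    class = "PeakMatrix")
  validate_peak_matrix(pm)
}

SAMPLE_ROLES <- c("study", "qc", "blank", "bridge")
PHENOTYPES <- c("cholestatic", "hepatocellular", "mixed", "recovered",
                "unknown")

#' Validate a PeakMatrix
#'
#' Checks dimension agreement between the intensity matrix and both metadata
#' tables, within-batch uniqueness of sample ids, the role enumeration,
#' feature id uniqueness and non-negativity of intensities.
#'
#' @param pm a `PeakMatrix`.
#' @return `pm`, invisibly unchanged, or a hard error naming the offence.
#' @export
validate_peak_matrix <- function(pm) {
  s <- pm$samples; f <- pm$features; x <- pm$intensities
  if (nrow(s) != nrow(x))
    stopf("sample axis mismatch: %d metadata rows vs %d matrix rows",
          nrow(s), nrow(x))
  if (nrow(f) != ncol(x))
    stopf("feature axis mismatch: %d metadata rows vs %d matrix columns",
          nrow(f), ncol(x))
  if (anyDuplicated(f$feature_id))
    stopf("duplicate feature_id: %s",
          paste(unique(f$feature_id[duplicated(f$feature_id)]), collapse = ", "))
  dup <- duplicated(paste(s$sample_id, s$batch_id))
  if (any(dup))
    stopf("duplicate sample_id within a batch: %s",
          paste(unique(s$sample_id[dup]), collapse = ", "))
  if (!all(s$role %in% SAMPLE_ROLES))
    stopf("unknown sample role(s): %s",
          paste(setdiff(unique(s$role), SAMPLE_ROLES), collapse = ", "))
  bridge <- unique(s$sample_id[s$role == "bridge"])
  for (b in bridge) {
    nb <- length(unique(s$batch_id[s$sample_id == b]))
    if (nb != 2L)
      stopf("bridge sample '%s' appears in %d batch(es), expected 2", b, nb)
  }
  if (any(x < 0, na.rm = TRUE))
    stopf("negative intensities are not allowed in a raw PeakMatrix")
  if (nrow(f) > 0 && any(stats::na.omit(f$mz) <= 0))
    stopf("feature m/z must be positive")
  invisible(pm)
}

#' @export
dim.PeakMatrix <- function(x) dim(x$intensities)

#' @export
print.PeakMatrix <- function(x, ...) {
  cat(sprintf("PeakMatrix: %d samples x %d features\n",
              nrow(x$intensities), ncol(x$intensities)))
  cat("  roles:  ", paste(sprintf("%s=%d", names(table(x$samples$role)),
                                  table(x$samples$role)), collapse = " "), "\n")
  cat("  batches:", paste(unique(x$samples$batch_id), collapse = " "), "\n")
  if (length(x$provenance))
    cat("  provenance:", length(x$provenance), "step(s), last:",
        utils::tail(x$provenance, 1), "\n")
  invisible(x)
}

# Append one provenance entry (append-only log).
add_provenance <- function(pm, msg) {
  pm$provenance <- c(pm$provenance, msg)
  pm
}

# Row / column subsetting that keeps metadata aligned. Internal.
pm_subset <- function(pm, samples = NULL, features = NULL) {
  if (!is.null(samples)) {
    pm$samples <- pm$samples[samples, , drop = FALSE]
    pm$intensities <- pm$intensities[samples, , drop = FALSE]
    rownames(pm$samples) <- NULL
  }
  if (!is.null(features)) {
    pm$features <- pm$features[features, , drop = FALSE]
    pm$intensities <- pm$intensities[, features, drop = FALSE]
    rownames(pm$features) <- NULL
  }
  pm
}

sample_cols <- c("sample_id", "patient_id", "injection_order", "batch_id",
                 "role", "timepoint_index", "phenotype_label")
feature_cols <- c("feature_id", "mz", "rt", "esi_mode", "annotation",
                  "metabolite_class", "metabolite_subclass", "excluded_flag")

#' Read a peak table and its metadata from tab-separated files
#'
#' Files are UTF-8 TSV with header rows; the intensity table has samples as
#' rows (first column `sample_uid`, ignored beyond ordering) and features as
#' columns. Empty intensity cells become `NA` and are reported in the
#' provenance log; the default pipeline policy drops such features before
#' modelling.
#'
#' @param path intensity TSV.
#' @param sample_meta_path sample metadata TSV.
#' @param feature_meta_path feature metadata TSV.
#' @param provenance_path optional provenance log to restore.
#' @return A validated [peak_matrix()].
#' @export
read_peak_table <- function(path, sample_meta_path, feature_meta_path,
                            provenance_path = NULL) {
  for (p in c(path, sample_meta_path, feature_meta_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  samples <- utils::read.delim(sample_meta_path, sep = "\t",
                               colClasses = NA, na.strings = "")
  features <- utils::read.delim(feature_meta_path, sep = "\t",
                                colClasses = NA, na.strings = "")
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           na.strings = "")
  x <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  # character/empty columns coerced to NA are caught by the validator
  samples$patient_id <- as.character(samples$patient_id %||% "")
  samples$patient_id[is.na(samples$patient_id)] <- ""
  for (col in c("annotation", "metabolite_class", "metabolite_subclass")) {
    features[[col]] <- as.character(features[[col]])
    features[[col]][is.na(features[[col]])] <- ""
  }
  if (ncol(x) != nrow(features))
    stopf("feature axis mismatch: %d matrix columns vs %d metadata rows",
          ncol(x), nrow(features))
  if (nrow(x) != nrow(samples))
    stopf("sample axis mismatch: %d matrix rows vs %d metadata rows",
          nrow(x), nrow(samples))
  colnames(x) <- features$feature_id
  prov <- if (!is.null(provenance_path) && file.exists(provenance_path))
    readLines(provenance_path) else character()
  n_na <- sum(is.na(x))
  pm <- peak_matrix(samples, features, x, prov)
  if (n_na > 0)
    pm <- add_provenance(pm, sprintf("read: %d empty intensity cells read as missing", n_na))
  pm
}

#' Write a PeakMatrix as tab-separated files
#'
#' Emits `intensities.tsv`, `samples.tsv`, `features.tsv` and
#' `provenance.txt` under `out_dir`. `read_peak_table()` on the emitted
#' files reproduces the object (metadata exactly, intensities to full
#' double precision via 17 significant digits).
#'
#' @param pm a `PeakMatrix`.
#' @param out_dir output directory, created if needed.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_peak_table <- function(pm, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stopf("cannot write to directory: %s", out_dir)
  paths <- c(intensities = file.path(out_dir, "intensities.tsv"),
             samples = file.path(out_dir, "samples.tsv"),
             features = file.path(out_dir, "features.tsv"),
             provenance = file.path(out_dir, "provenance.txt"))
  x <- format(pm$intensities, digits = 17, trim = TRUE, scientific = TRUE)
  x[is.na(pm$intensities)] <- ""
  df <- data.frame(sample_uid = paste(pm$samples$sample_id,
                                      pm$samples$batch_id, sep = "@"),
                   x, check.names = FALSE)
  colnames(df) <- c("sample_uid", pm$features$feature_id)
  utils::write.table(df, paths[["intensities"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(pm$samples, paths[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(pm$features, paths[["features"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  writeLines(pm$provenance, paths[["provenance"]])
  invisible(paths)
}

#' Concatenate positive- and negative-mode peak matrices feature-wise
#'
#' Both matrices are restricted to their study samples, which must cover the
#' same `sample_id` set (each ESI mode is acquired, corrected and filtered in
#' its own batches first). Feature ids are prefixed `pos_` / `neg_`; the
#' sample order of `pm_pos` is retained.
#'
#' @param pm_pos,pm_neg `PeakMatrix` objects for ESI+ and ESI-.
#' @return Combined `PeakMatrix` of the study samples.
#' @export
combine_modes <- function(pm_pos, pm_neg) {
  sp <- pm_pos$samples$role == "study"
  sn <- pm_neg$samples$role == "study"
  idp <- pm_pos$samples$sample_id[sp]
  idn <- pm_neg$samples$sample_id[sn]
  if (!setequal(idp, idn)) {
    only_p <- setdiff(idp, idn); only_n <- setdiff(idn, idp)
    stopf("study sample sets differ between modes (only ESI+: %s | only ESI-: %s)",
          paste(only_p, collapse = ","), paste(only_n, collapse = ","))
  }
  pos <- pm_subset(pm_pos, samples = which(sp))
  neg <- pm_subset(pm_neg, samples = which(sn))
  neg <- pm_subset(neg, samples = match(pos$samples$sample_id,
                                        neg$samples$sample_id))
  fp <- pos$features; fp$feature_id <- paste0("pos_", fp$feature_id)
  fn <- neg$features; fn$feature_id <- paste0("neg_", fn$feature_id)
  x <- cbind(pos$intensities, neg$intensities)
  colnames(x) <- c(fp$feature_id, fn$feature_id)
  pm <- peak_matrix(pos$samples, rbind(fp, fn), x,
                    c(pos$provenance, neg$provenance))
  add_provenance(pm, sprintf("combine_modes: %d ESI+ and %d ESI- features",
                             nrow(fp), nrow(fn)))
}

#' Split a combined matrix back into its ESI modes
#'
#' Inverse of [combine_modes()] based on the `pos_` / `neg_` feature-id
#' prefixes.
#'
#' @param pm combined `PeakMatrix`.
#' @return list with elements `pos` and `neg`.
#' @export
split_modes <- function(pm) {
  is_pos <- startsWith(pm$features$feature_id, "pos_")
  is_neg <- startsWith(pm$features$feature_id, "neg_")
  if (!all(is_pos | is_neg))
    stopf("features without a mode prefix: %s",
          paste(utils::head(pm$features$feature_id[!(is_pos | is_neg)], 5),
                collapse = ", "))
  strip <- function(sub, prefix) {
    sub$features$feature_id <- sub("^(pos|neg)_", "", sub$features$feature_id)
    colnames(sub$intensities) <- sub$features$feature_id
    sub
  }
  list(pos = strip(pm_subset(pm, features = which(is_pos))),
       neg = strip(pm_subset(pm, features = which(is_neg))))
}

# Drop features with any missing value among study samples (default policy
# before modelling; upstream peak filling is out of scope).
drop_missing_features <- function(pm) {
  st <- pm$samples$role %in% c("study", "bridge")
  bad <- colSums(is.na(pm$intensities[st, , drop = FALSE])) > 0
  if (any(bad)) {
    pm <- pm_subset(pm, features = which(!bad))
    pm <- add_provenance(pm, sprintf("drop_missing_features: removed %d feature(s) with missing study values",
                                     sum(bad)))
  }
  pm
}
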