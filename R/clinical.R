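#' Clinical R-score of a DILI episode
#'
#' `R = ([ALT]/[ALT]_UNL) / ([ALP]/[ALP]_UNL)`: the fold-elevation of serum
#' alanine aminotransferase over the fold-elevation of alkaline phosphatase,
#' each relative to its upper normal limit (UNL). Values above 5 indicate
#' predominantly hepatocellular injury, below 2 cholestatic injury, and
#' values in between a mixed pattern. The UNL defaults (56 U/L for ALT,
#' 147 U/L for ALP) are the thresholds the rule-based phenotype
#' classification uses; both can be overridden to match local laboratory
#' reference ranges.
#'
#' @param alt serum ALT activity, U/L (vectorized).
#' @param alp serum ALP activity, U/L; must be strictly positive.
#' @param alt_unl,alp_unl upper normal limits, U/L.
#' @return Numeric vector of unrounded R-scores.
#' @examples
#' r_score(68, 277)   # ~0.64
#' r_score(2293, 188) # ~32.0
#' @export
r_score <- function(alt, alp, alt_unl = 56, alp_unl = 147) {
  if (any(is.na(alt)) || any(is.na(alp)))
    stopf("ALT/ALP must not be missing for an R-score")
  if (any(alt < 0)) stopf("ALT must be non-negative")
  if (any(alp <= 0)) stopf("ALP must be strictly positive (division by zero)")
  if (alt_unl <= 0 || alp_unl <= 0) stopf("UNLs must be positive")
  (alt / alt_unl) / (alp / alp_unl)
}

#' Rule-based DILI phenotype from clinical chemistry
#'
#' Applies, in order: recovered if `ALT < ALT_UNL` and `ALP < ALP_UNL`;
#' cholestatic if `ALP >= ALP_UNL` and `R < 2`; hepatocellular if
#' `ALT >= ALT_UNL` and `R >= 5`; mixed if `2 <= R < 5`. The printed rules
#' leave two gaps: `R` exactly 2 (assigned to mixed here, keeping the strict
#' inequalities of the other classes intact) and elevated-enzyme records
#' matching no rule (e.g. `R < 2` with normal ALP), which are labelled
#' `unclassifiable` rather than silently forced into a class. The function
#' is total: every record receives exactly one label.
#'
#' @inheritParams r_score
#' @return Character vector over `{cholestatic, hepatocellular, mixed,
#'   recovered, unclassifiable}`.
#' @export
classify_phenotype <- function(alt, alp, alt_unl = 56, alp_unl = 147) {
  r <- r_score(alt, alp, alt_unl, alp_unl)
  out <- rep("unclassifiable", length(r))
  out[alt < alt_unl & alp < alp_unl] <- "recovered"
  todo <- out == "unclassifiable"
  out[todo & alp >= alp_unl & r < 2] <- "cholestatic"
  todo <- out == "unclassifiable"
  out[todo & alt >= alt_unl & r >= 5] <- "hepatocellular"
  todo <- out == "unclassifiable"
  out[todo & r >= 2 & r < 5] <- "mixed"
  out
}

#' Append R-score and phenotype label to a clinical table
#'
#' @param clinical data frame with at least `alt` and `alp` columns (U/L).
#' @inheritParams r_score
#' @return The table with `r_score` and `phenotype_label` columns appended.
#' @export
add_clinical_scores <- function(clinical, alt_unl = 56, alp_unl = 147) {
  if (!all(c("alt", "alp") %in% names(clinical)))
    stopf("clinical table needs 'alt' and 'alp' columns")
  clinical$r_score <- r_score(clinical$alt, clinical$alp, alt_unl, alp_unl)
  clinical$phenotype_label <- classify_phenotype(clinical$alt, clinical$alp,
                                                 alt_unl, alp_unl)
  clinical
}
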