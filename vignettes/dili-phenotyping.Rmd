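---
title: "Phenotyping drug-induced liver injury from serum LC-MS metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping drug-induced liver injury from serum LC-MS metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Drug-induced liver injury (DILI) is classified at the bedside as
cholestatic, hepatocellular or mixed from two serum enzymes, via the
R-score `([ALT]/[ALT]_UNL) / ([ALP]/[ALP]_UNL)`. The score collapses a
complex, evolving injury into one enzyme ratio: it is insensitive to some
injury mechanisms, not liver-specific, and slow to track recovery because
of the long transaminase half-life. The serum metabolome offers a richer
readout: cholestasis elevates circulating conjugated bile acids, and active
hepatocellular injury depresses glycerophosphocholines and
-ethanolamines relative to recovered patients. `dilimet` turns an
untargeted LC-MS peak table plus liver chemistry into (i) quality-controlled
intensities, (ii) three one-vs-rest PLS-DA class predictions per sample,
and (iii) a position on the cholestatic / hepatocellular / recovered
ternary simplex that can be followed over a patient's visits.

## Preprocessing model

**QC-SVRC drift correction.** Instrument response drifts smoothly with
injection order within an acquisition batch. Pooled QC samples, injected
every 8 samples (batch 1) and every 10 (batch 2), sample that drift. For
each feature and batch we regress QC intensity on injection order with an
epsilon-insensitive support-vector machine (RBF kernel, via LIBSVM/e1071):

- `C` (regularization) is pinned to the median QC intensity of the
  feature - the method's convention, putting the penalty on the intensity
  scale of the feature;
- `epsilon` (tube half-width, AU) is searched over 2.5-8% of the QC
  median - the expected instrumental precision band - in 8 linear steps;
- `gamma` (kernel width per squared rescaled-order unit) over `[1, 1e4]`
  in 13 log-spaced steps;
- the `(epsilon, gamma)` node minimizing the leave-one-out RMSECV over the
  QCs wins; exact ties go to the smallest `gamma`, then the smallest
  `epsilon`, preferring the smoothest trend.

Injection order is rescaled to `[0, 1]` within each batch before kernel
evaluation, so `gamma` means the same thing in batches of different
lengths. Correction is the multiplicative ratio `x * C / trend(order)`,
which keeps intensities positive and normalizes each feature to its QC
reference level; trend values below 1% of `C` are floored there (with a
warning) rather than allowed to blow the ratio up. A feature whose QC
intensities are exactly constant gets the identity correction without a
grid search. Leave-one-out errors are computed by LIBSVM's internal
cross-validation (the fold partition is fixed for leave-one-out; we pin
the RNG around the call so the floating-point accumulation order, and
hence the last digits of the RMSECV, are reproducible, and restore the
caller's RNG state).

**Filters.** After correction:

- *D-ratio\** (robust dispersion ratio): `100 * mad(QC) / mad(study)`,
  computed within each batch (its QCs against its study samples) with the
  worst batch deciding; features above 20% are removed. We compute it
  per batch because the filter runs before between-batch scaling, and
  pooling QCs across batches would count the between-batch offset as
  technical dispersion. Note that with ~12 QCs the MAD ratio is a noisy
  estimator; on the default synthetic study (technical RSD ~6-7% after
  correction, biological CV 60%) it removes roughly a quarter to a third
  of features. That is the filter working as defined, not a defect: a
  feature whose technical spread is a fifth of its biological spread sits
  near the 20% line.
- *Blank filter*: a feature is removed iff `10 x max(blank)` exceeds the
  median over study samples. Applied to post-correction intensities by
  default (the rule is a ratio, so the choice is nearly immaterial; it is
  configurable).
- *Group-intensity filter*: keep a feature iff its within-group median
  exceeds 15000 AU (strictly) in at least one phenotype group.
- Features flagged as drug metabolites or food components are dropped by
  annotation flag; re-deriving those flags is out of scope.
- Missing intensities are tolerated on input; the default policy drops any
  feature with a missing study-sample value before modelling (peak
  filling belongs to the upstream peak-detection software).

**Between-batch scaling.** Fifteen bridge samples re-injected in batch 2
anchor the batches: per feature and batch, the factor is the batch's
bridge median over the pooled bridge median, and all intensities in the
batch are divided by it. This makes per-feature bridge medians exactly
equal across batches. The batch-1 copies of the bridge samples are then
dropped (keeping the batch-2 re-injections, which mirrors how the bridge
set was acquired) and the survivors become ordinary study samples.

## Statistical modelling

**Univariate screen.** Welch's unequal-variance t per feature with
Benjamini-Hochberg FDR at 0.05, applied within each pairwise comparison
(cholestatic vs hepatocellular, each vs recovered) separately, because the
discriminant feature sets are reported per comparison. Two-sided
throughout.

**PLS-DA.** NIPALS with deflation of both blocks; class membership coded
0/1 (decision threshold 0.5), X autoscaled and y centered *inside the
fit*, so every cross-validation split rescales on its own training data -
scaling on the full data before CV would leak the held-out samples'
distribution into training. The regression vector is `W (P'W)^-1 Q'`. VIP
scores use the standard formula whose squares average to exactly 1;
VIP > 1 defines each model's discriminant set.

**Subjectwise double CV.** Patients, not samples, are randomized to folds
(stratified on the patient's majority label), so repeated samples of one
patient never straddle train and test. The outer loop (7 folds) holds out
test patients; the inner loop (5 folds) picks the LV count maximizing CV
classification accuracy (ties to fewest LVs, capped at 10); a model with
that count, fit on all non-test data, predicts the held-out fold. Every
sample gets exactly one out-of-sample prediction, and by construction no
model ever saw its predicted sample's patient. Fold counts of 7/5 are
package defaults chosen to keep a handful of patients per fold at the
scale of a ~60-80-patient study; they are configurable.

**Permutation test.** AUROC significance uses
`p = (1 + #{perm >= observed}) / (n_perm + 1)` over 100 label
permutations by default. Labels are permuted at the *patient* level:
because longitudinal patients legitimately change class as they recover,
per-patient label sequences have unequal lengths and cannot be swapped
verbatim; instead each patient's majority label is reassigned across
patients and inherited by all their samples, which preserves the
repeated-measures structure under the null.

**One-vs-rest suite.** Three binary models (cholestatic, hepatocellular,
recovered, each vs the rest). Mixed-type samples are excluded from all
training and receive plain predictions from the three full models; the
training classes receive their double-CV predictions. A final 2-LV PLS2
model on the union of the three VIP > 1 sets provides the score/loading
overview.

## Ternary integration

PLS predictions are unbounded, so each is clipped to `[0, 1]` and the
triple normalized by its sum: the shares `(c, h, r)` position the sample
in an equilateral triangle with cholestatic at the origin, hepatocellular
at (1, 0) and recovered at the apex. The all-zero triple has no direction;
it maps to the centroid and carries an explicit `indeterminate` flag so
plots never silently drop samples (the printed procedure does not define
this case; we chose the visible fallback). Sum-normalization is the
minimal reading of "relative constrained y values"; no other rescaling is
applied. The distance from a sample to the recovered apex - dimensionless
in `[0, 1]` for the unit side - is the recovery readout; per-patient
time-ordered coordinates form trajectories (duplicate patient/timepoint
pairs are an error).

## The synthetic study generator

There is no public peak table for this kind of study, so the generator is
a first-class module: every downstream stage is exercised on data whose
ground truth is known. It emulates:

- two acquisition batches, QCs every 8 (batch 1) / 10 (batch 2)
  injections plus a closing QC (a minimum of 4 QCs per batch is enforced
  because the SVR needs support), blanks at batch end (2 and 6), 15
  bridge samples re-injected in batch 2 with the same underlying true
  intensity;
- baseline intensities log-uniform over `[1e4, 1e6]` AU, so the 15000 AU
  group filter is exercised on both sides;
- phenotype effects as multiplicative log2 shifts versus the recovered
  baseline: bile-acid-like features +2 (cholestatic) / +0.5
  (hepatocellular); glycerophospholipid-like features -1 / -1.5. The
  magnitudes are free simulator parameters - the source study reports
  directions, not effect sizes;
- mixed patients as a per-patient convex blend (uniform on 0.3-0.7) of
  the two effect vectors;
- recovery as geometric decay of the effect weight per visit
  (`(1 - rate)^(t-1)`, default rate 0.4, 15% of multi-visit DILI patients
  non-recovering); a sample is labelled with the patient's phenotype
  while its weight is at least 0.5 and `recovered` below;
- between-sample biological variation, log-normal with CV 0.6 - serum
  metabolite inter-individual CVs typically run 40-100%, and this is the
  denominator the D-ratio* filter divides by;
- within-batch drift as a centered random cubic of injection order scaled
  to a maximum relative deviation of 0.3 (a constant multiplier is a
  batch offset, generated separately with log-normal sd 0.15 and removed
  by bridge scaling, not drift; the cubic is deliberately a different
  functional family from the RBF corrector so the correction test cannot
  be self-fulfilling);
- technical noise, log-normal with CV 0.1; blanks at 0.2-1% of baseline
  except 5 planted contaminants near baseline level;
- clinical chemistry drawn from phenotype-conditional log-normal
  distributions anchored on the study's published group means (e.g. ALP
  341 U/L cholestatic, ALT 744 U/L hepatocellular), truncated so the
  R-score rules reproduce the planted label; AST, GGT, bilirubin and
  albumin are similarly anchored.

What the generator does *not* emulate: correlated metabolite modules,
isotopes/adducts, retention-time structure, missingness mechanisms,
treatment effects, or heavy-tailed clinical outliers. Tests passing on
synthetic data therefore demonstrate that the machinery is correct and
recovers planted truth under realistic dispersion and drift - not that
real patients separate with AUROC 0.99; on real data the separation is
set by biology, not by the pipeline.

## Numerical choices and edge cases

- Clinical rule gaps are explicit: R exactly 2 with elevated enzymes is
  assigned to mixed (the printed rules use strict inequalities on both
  sides of 2); an elevated-enzyme record matching no rule (e.g. R < 2
  with normal ALP) is `unclassifiable`, never silently forced.
- The ALT/ALP upper normal limits (56/147 U/L) are the classification
  thresholds themselves, verified by recomputing the published follow-up
  R-scores; both are overridable.
- An SVR whose epsilon tube encloses all QC points has zero support
  vectors; its solution is the constant offset `-rho`, handled explicitly.
- NIPALS stops early (with fewer LVs than requested) when the response
  residual vanishes; the PLS2 inner loop iterates to `1e-10` relative
  tolerance, erroring after 500 iterations.
- Zero-variance features inside a training split get scale 1 (their
  centered values are zero and contribute nothing).
- One master seed fans out to per-stage child seeds (folds, inner folds,
  permutations, generator), so stages can be re-run in isolation and a
  full `run_all()` is bit-reproducible.

## Problem sizes in the test suite

The packaged tests run the complete pipeline on the generator's default
study (60 patients, ~180 samples plus QCs/blanks/bridges, 300 features,
two batches) with the full 8 x 13 QC-SVRC grid, 50 label permutations for
the acceptance run, and brute-force oracles on reduced grids (3 x 4) over
50 random QC series; unit tests use a 20-patient, 40-feature study. These
sizes were chosen so the whole suite exercises every stage at realistic
dimensionality in a few minutes on one core.

## Known limitations

- The package starts from an aligned peak table; peak detection,
  integration, alignment and MS/MS annotation are upstream and out of
  scope.
- D-ratio* estimates from ~12 QCs are noisy; with strict 20% the filter
  is conservative (see above). If more QCs are available the estimate
  sharpens automatically.
- The permutation scheme permutes patient majority labels; under extreme
  within-patient label heterogeneity the null is approximate.
- `select_n_lv` optimizes classification accuracy, which plateaus on
  well-separated data; the tie-break to fewest LVs is what keeps models
  small in that regime.
- No imputation beyond the drop policy, and no alternative batch
  correction methods (LOESS, ComBat) - the QC-SVRC ratio is the method
  implemented.
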