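---
title: "Whole-lesion ADC histogram profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-lesion ADC histogram profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adchist)
```

## The problem

High-grade gliomas — anaplastic astrocytoma (WHO grade III) and glioblastoma
(WHO grade IV) — look alike on conventional MRI, yet their prognoses differ
sharply. Diffusion-weighted MRI yields a quantitative map of the apparent
diffusion coefficient (ADC, mm²/s), which falls where cellularity rises.
Whole-lesion histogram profiling summarises the distribution of all ADC
values inside a 3-D tumour mask with thirteen parameters — mean, minimum,
maximum, the 10th/25th/75th/90th percentiles, median, mode and standard
deviation (first order), plus skewness, kurtosis and entropy (second order)
— and asks whether those parameters separate tumour grades, track the Ki-67
proliferation index, or predict MGMT promotor methylation.

`adchist` implements that analysis end to end: volume and mask I/O, feature
extraction, normality-gated group statistics, ROC/Youden cut-off analysis,
and a synthetic cohort generator so that every stage is testable without
clinical data.

## Units

ADC appears in the literature at several scales. Internally every volume is
converted to canonical mm²/s at read time using the declared scale of the
source file (`unit_scale`, e.g. `"1e-6"` for integer maps storing
10⁻⁶ mm²/s per unit). All *reporting* uses 10⁻⁵ mm²/s, the scale at which
glioma histogram statistics are conventionally tabulated: a mean ADC of
1.3757 × 10⁻³ mm²/s prints as 137.57, and a cut-off printed as
0.0003156 mm²/s is 31.56 report units. Pinning one canonical unit with an
explicit report scale removes a whole class of scale-confusion errors.
Integer-valued sources additionally retain their stored array, so writing a
volume back at its source scale is bit-lossless (naive decimal rescaling of
doubles can lose an ULP; see `report_voxels()`).

## Image ingestion and mask handling

Volumes are read from NIfTI-1 (via RNifti) or from a directory holding one
DICOM series; DICOM slices are ordered by the projection of their
ImagePositionPatient onto the slice normal, so file naming is irrelevant.
The DICOM parser handles the uncompressed little-endian encodings
(implicit and explicit VR) that exported ADC maps use.

Lesion masks drawn on another grid (typically a T1-weighted series) are
brought onto the ADC grid by mapping each ADC voxel centre through the two
affines and taking the nearest-neighbour mask value — binary masks must
stay binary, so no interpolation that would create fractional labels is
used, and no intensity-based registration is attempted (the affines are
trusted). A mask that resamples to emptiness signals that the lesion lies
outside the ADC field of view and raises a degenerate-mask error rather
than returning a silent zero-voxel sample.

Within the mask, non-finite voxels are dropped and counted. Voxels with
ADC = 0 are **kept**: true near-zero ADC occurs in dense or artefactual
lesion cores, and cohort tables report lesion minima as low as
0.10 × 10⁻⁵ mm²/s, so dropping zeros would bias the minimum upward. The
mask is taken as given; whether necrotic or cystic cores belong in the
region of interest is a segmentation decision upstream of this package.

## The thirteen parameters and their conventions

Published histogram-profiling studies rarely print their numerical
conventions, so each choice here is explicit, documented and (where
reasonable) configurable:

* **Percentiles** interpolate linearly between order statistics
  (`quantile(type = 7)`).
* **SD** uses denominator n − 1.
* **Skewness** is the biased moment coefficient m₃/m₂^{3/2} and
  **kurtosis** the Pearson (non-excess) m₄/m₂², so a Gaussian sample gives
  kurtosis 3. Reported cohort kurtosis ranges (roughly 1.4–23, mean ≈ 5)
  are consistent with this convention rather than with excess kurtosis.
  Small-sample corrections are pointless at lesion voxel counts (10³–10⁵)
  and are not applied.
* **Mode and entropy** come from an equal-width histogram with 128 bins
  spanning the lesion's own [min, max]; the mode is the centre of the
  fullest bin (ties to the lowest bin, because a raw-value mode would
  depend on storage precision), and entropy is −Σ pᵢ log₂ pᵢ over
  non-empty bins, in bits. Observed cohort entropy ranges (≈3.3–5.6) are
  consistent with log₂ and order-100 bins. The bin count is a configuration
  knob recorded in every output row. Because no published binning rule
  exists, *numerical* agreement of mode/entropy with any particular
  published per-patient table is not guaranteed — these two fields are
  convention-dependent, while their invariants (permutation invariance,
  exact invariance of entropy under affine rescaling, 0 ≤ H ≤ log₂ bins)
  are guaranteed and tested.

A zero-variance sample has no defined skewness or kurtosis; those fields
return `NA` with a warning while mode (the constant) and entropy (0) are
still produced.

## The statistical stage

Every test mirrors the serial-univariate design of classical
histogram-profiling studies:

1. **Normality gate.** Shapiro-Wilk at α = 0.05; a sample is "Gaussian"
   iff the test does not reject. Dispatch defaults to *per-group* gating
   (a t-test requires both groups to pass); *cohort-wide* gating — testing
   the pooled values once, the convention some clinical packages used — is
   available via `gate_mode` for reproducing such analyses.
2. **Two-group comparisons** (grade III vs IV; MGMT methylated vs
   unmethylated, unknowns dropped): Student's pooled-variance t-test when
   the gate passes (Welch by flag), otherwise a two-sided Mann-Whitney U —
   exact enumeration when both groups have n ≤ 8 without ties, else the
   normal approximation with continuity and tie correction. Group means,
   SDs and t-based 95% CIs are always reported, whichever test ran.
3. **Ki-67 correlation**: Pearson only if both variables pass the gate on
   the pooled cohort, otherwise Spearman with midranks; two-sided p via
   the t-approximation on r.
4. **ROC analysis** for each parameter that separates the grades: the AUC
   is computed through the Mann-Whitney identity U/(n₁n₂) with ties
   counted ½ (this equality is asserted to 10⁻¹² in the tests), polarity
   oriented so AUC ≥ 0.5 and recorded. The 95% CI uses the Hanley-McNeil
   standard error by default (the closed form classical packages used),
   DeLong's covariance-based SE by option; the p-value tests AUC = 0.5
   with z = (AUC − 0.5)/SE.
5. **Youden cut-off**: J = sensitivity + specificity − 1 maximised over
   midpoints between adjacent distinct observed values plus ±∞. Ties on J
   break toward higher specificity, then higher threshold — in a
   grading context a false "glioblastoma" label is the costlier error, so
   specificity is preferred at equal J. Cut-offs are reported in both
   report units and mm²/s.

No multiple-testing correction is applied by default, matching the
exploratory serial-testing design this mirrors (and its acknowledged
alpha-inflation limitation); `multiplicity = "holm"` bases the
significance flags on Holm-adjusted p-values instead.

Two wrinkles worth knowing: published normality listings of this design
are sometimes self-contradictory (the same parameter listed as both
Gaussian and non-Gaussian, or the inequality direction misprinted), so
dispatch always follows the *computed* Shapiro-Wilk result, never a text
listing. And printed "(SD)" columns in such tables sometimes mix standard
deviations with standard errors; `adchist` outputs label the two
explicitly rather than guessing.

`summary_ttest()` computes the pooled t-test from printed group means, SDs
and sizes alone, so published group-level tables can be checked without
per-patient data; the transcribed reference summaries ship in
`reference_group_summaries()`.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture dump. Its
defaults emulate a 56-patient high-grade-glioma cohort (11 grade III, 45
grade IV — the class imbalance matters for power behaviour):

* **Grade III** lesions draw voxels from a single normal component
  truncated at 0, per-tumour location ~ N(137, 22) × 10⁻⁵ mm²/s and
  within-tumour SD ~ N(23, 5) × 10⁻⁵.
* **Grade IV** lesions are a three-component truncated-normal mixture:
  hypercellular low-ADC component at 70, bulk at 130, necrotic/edematous
  high-ADC at 220 (× 10⁻⁵), component SDs 15/18/25, with per-tumour
  Dirichlet(4, 26, 4) weights, a per-tumour location shift ~ N(0, 10) and
  a multiplicative SD jitter (SD 0.15). Analytically this mixture has
  within-tumour SD ≈ 41 × 10⁻⁵ and skewness ≈ 0.8, so grade IV shows the
  lower minimum/p10 and higher maximum/SD/skewness that the analysis is
  meant to detect.
* **Ki-67** = −16 + 1.15 × (planted per-tumour SD, report units) +
  N(0, 17), clipped to [0, 100]; this coupling was calibrated (analytically,
  then confirmed by simulation) to give a cohort Spearman correlation near
  0.45 between ADC SD and Ki-67. **MGMT** is an independent Bernoulli(0.5),
  deliberately uncoupled: the MGMT comparison should come out null.
* **Voxel counts** per lesion are log-uniform on 10³–10⁵ — an assumption,
  not a reported value; lesion voxel counts are rarely published.

Reproducibility: one global seed; each patient's substream seed is a fixed
affine hash of (seed, patient index), so enlarging the cohort never
reshuffles existing patients.

Voxel-level volumes are rendered *marginal-first*: an ellipsoidal mask is
filled with a smoothed Gaussian random field whose ranks are mapped through
the patient's mixture quantile function. The analysis consumes only the
within-mask marginal distribution, so matching that marginal exactly — while
still giving spatially smooth, visually plausible lesions — is the correct
fidelity target; no biophysical growth or acquisition modelling is
attempted. Consequences worth stating: passing tests demonstrate the
statistical machinery on data with exactly the assumed structure; they say
nothing about scanner noise, distortion, perfusion contamination at low
b-values, or mask-placement variability, none of which are simulated.

```{r example}
cohort <- simulate_feature_cohort(synthetic_config(rng_seed = 1))
tabs <- build_tables(cohort)
tabs$table2[tabs$table2$significant, c("parameter", "p_value", "test_used")]
glance(roc_analysis(cohort, "ADCsd"))
```

## Numerical choices and degenerate inputs

* AUC ties count ½; midranks are used throughout the rank machinery.
* Youden's J is compared with a 10⁻¹² tolerance when breaking ties:
  sensitivities and specificities are ratios of small integers, and exact
  floating-point comparison of J values computed from different ratios
  would break ties arbitrarily.
* Constant samples: non-Gaussian by convention (with a warning), p = 1 for
  equal-mean degenerate summary t-tests, correlation against a constant is
  an error, all-tied ROC gives AUC 0.5.
* Masks resampled to empty, all-non-finite samples, groups below 3
  patients, and ellipsoids exceeding the phantom grid each raise a typed
  condition rather than propagating NaN.

## Problem sizes in the test suite

The suite verifies oracle equivalences on samples up to 1000 voxels,
type-I calibration of the gated comparison over 2000 null simulations
(n = 20 per group), null-mode calibration of the full table-2 machinery
over 2000 reduced cohorts (10 + 10 patients, 300–800 voxels each), and the
population structure of the default generator over a 50-seed ensemble —
sizes chosen to bound Monte-Carlo error meaningfully (binomial SE ≈ 0.005
at 2000 draws) while keeping a full run in single-digit minutes.

## Known limitations

* DICOM support covers uncompressed little-endian single-frame series —
  the form in which ADC maps are exported — not compressed transfer
  syntaxes, enhanced multi-frame objects, or DICOM-SEG masks.
* Mode and entropy are binning-convention dependent (above); comparisons
  across software require matching the convention, and the bin count is
  therefore embedded in every output row.
* The gate-then-test design inherits the usual criticism of pre-testing
  normality; it is implemented because it is the design being reproduced,
  with the gate mode and test variant exposed for sensitivity analysis.
* Correlations and comparisons are univariate by design; no multivariable
  classifier, survival modelling or IDH stratification is in scope.
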