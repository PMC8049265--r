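# adchist

Whole-lesion ADC histogram profiling for high-grade glioma, with
normality-gated cohort statistics and ROC/Youden cut-off analysis.

## What it is for

Anaplastic astrocytoma (WHO grade III) and glioblastoma (WHO grade IV) are
hard to tell apart on conventional MRI. Diffusion-weighted imaging maps the
apparent diffusion coefficient (ADC, mm²/s), which drops where tumour
cellularity rises, and *whole-lesion histogram profiling* condenses every
ADC voxel inside a 3-D tumour mask into thirteen parameters:

- first order: ADC<sub>mean</sub>, ADC<sub>min</sub>, ADC<sub>max</sub>,
  p10, p25, p75, p90, median, mode, SD;
- second order: skewness (m₃/m₂^{3/2}), kurtosis (Pearson m₄/m₂², normal
  = 3), entropy (−Σ pᵢ log₂ pᵢ over a 128-bin equal-width histogram, bits).

The cohort layer then reproduces the classical analysis around these
features: Shapiro-Wilk-gated dispatch between Student's t and Mann-Whitney
U for grade III vs IV and MGMT methylated vs unmethylated comparisons,
gated Pearson/Spearman correlation with the Ki-67 proliferation index, and
for grade-discriminating parameters an empirical ROC whose AUC is computed
through the Mann-Whitney identity AUC = U/(n₁n₂) (ties ½), with
Hanley-McNeil (or DeLong) confidence intervals and a Youden-index optimal
cut-off (ties broken toward higher specificity).

The package is aimed at neuroimaging researchers who want this analysis as
tested, scriptable building blocks — including a synthetic cohort generator
that emulates the grade-dependent voxel-distribution structure (grade IV:
low-ADC hypercellular + bulk + high-ADC necrotic components, hence lower
minimum/p10, higher maximum/SD/skewness, Ki-67 coupled to ADC SD), so every
stage runs and is testable without any clinical data.

## Worked example

```r
library(adchist)

cohort <- simulate_feature_cohort(synthetic_config(rng_seed = 1))
tabs   <- build_tables(cohort)
tabs$table2[tabs$table2$significant, c("parameter", "mean1", "mean2", "test_used", "p_value")]
#>   parameter  mean1   mean2      test_used  p_value
#> 1    ADCmin  44.0    20.975      student_t 5.05e-04
#> 2    ADCmax 216.    296.236 mann_whitney_u 6.69e-07
#> 3    ADCp10 100.     84.408      student_t 3.16e-03
#> 5     ADCsd  21.9    39.525      student_t 1.56e-15
#> 7  Skewness  0.0071   0.743 mann_whitney_u 1.13e-06
#> 9      ki67  15.1    30.538      student_t 9.60e-03
```

Mean columns are in 10⁻⁵ mm²/s: the grade III group averages an ADC SD of
21.9 against 39.5 for grade IV — the glioblastomas are the more
heterogeneous lesions, and the same asymmetry shows in the extremes
(lower minimum, higher maximum) and the positive skewness.

```r
roc_analysis(cohort, "ADCsd")
#> <adc_roc> ADCsd (positive: IV, higher_positive): AUC = 0.9980 [0.9882-1.0000], p = 0
#>   Youden cut-off 31.74: sensitivity 0.98, specificity 1.00

tidy(correlate_ki67(cohort, "ADCsd"))
#>   parameter   method     r  p_value  n
#> 1     ADCsd spearman 0.573 3.99e-06 56
```

An ADC SD at or above 31.74 × 10⁻⁵ mm²/s (0.000317 mm²/s) flags grade IV
with specificity 1.00 on this cohort, and ADC SD correlates positively
with Ki-67 — the structure the generator plants and the analysis is built
to detect.

For imaging data, the same pipeline starts from files:

```r
profiles <- run_extract(adc_paths, mask_paths,
                        config = run_config(unit_scale_in = "1e-6"))
run_analyze("features_with_labels.csv", "report/")   # tables, ROC points, figures
```

`inst/exec/adchist.R` exposes `extract` / `analyze` / `simulate`
subcommands for shell use. Published group-level summary tables can be
checked without per-patient data via `summary_ttest()` and
`reference_group_summaries()`.

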