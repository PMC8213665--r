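# qreportr

Quantitative brain-volumetry reports and multi-rater study analysis in R.

Radiologists assessing dementia on MRI must judge whether regional volume
loss is abnormal for the patient's age — a task with known interrater
variability, especially for subtle atrophy in younger patients.
**qreportr** implements the two halves of evaluating a quantitative
decision aid for that task:

1. **The report pipeline.** A per-region *normative model* is fitted to a
   healthy reference population by ordinary least squares,

   *v* = β₀ + β₁·age + β₂·sex + β₃·TIV + ε,  ε ~ N(0, σ²),

   and a new subject's volume is standardised, *z* = (v − βx)/σ, then
   mapped through a CDF (exact Gaussian 100·Φ(z) by default; a
   1.702-scaled logistic approximation and a Richards generalised
   logistic fitted to the residual ECDF are selectable) to a percentile
   of the healthy population. The single-page report shows hippocampal
   percentiles, brain parenchymal fraction BPF = (GM + WM)/TIV against
   normative age curves, SNR/CNR quality metrics, and a log-radial,
   traffic-light *rose plot* of regional percentiles.

2. **The reader-study analysis.** For a forced-choice with/without-report
   study (normal/abnormal, then AD vs FTD), the package computes per-rater
   confusion counts; sensitivity = TP/(TP+FN)·100, specificity =
   TN/(TN+FP)·100, accuracy = (TP+TN)/total·100; McNemar and paired t
   tests with pooled-SD Cohen's d; Cohen's κ = (p₀ − pₑ)/(1 − pₑ)
   against the gold standard; Cronbach's α and ICC(3,1)/(3,k) across
   raters; a four-way mixed ANOVA of confidence (report × normality ×
   correctness × experience) with partial η²; and paired-design sample
   sizes from noncentral-t power.

Synthetic generators (normative cohort of n = 461, a 45-scan test set
with AD/FTD atrophy patterns, randomised rating schedules, simulated
raters) make every step testable without imaging data.

## Worked example

```r
library(qreportr)
library(dplyr)

# fit the normative model on a synthetic healthy reference population
ref   <- simulate_normative_population(seed = 42)   # n = 461
model <- fit_normative_model(ref)

# score one simulated AD patient and render their report
cohort <- simulate_test_cohort(seed = 42)           # 15 / 16 / 14
subj   <- cohort[cohort$group == "AD", ][1, ]
volume_percentiles(model, subj,
                   regions = c("hippocampus_left", "hippocampus_right"))
#>   subject_id region            volume      z percentile
#> 1 T016       hippocampus_left    2.59 -1.45        7.30
#> 2 T016       hippocampus_right   2.80 -0.846      19.9

bundle <- build_report_bundle(model, fit_bpf_model(ref), subj,
                              qc = qc_metrics(120, 180, 10))
bundle
#> Quantitative report bundle
#>   age/sex:            59.2 / female
#>   hippocampus (L/R):  7.3 / 19.9 %ile
#>   BPF:                0.747 (11.2 %ile)
#>   rose sectors:       14
render_report(bundle, "report.html")   # deterministic single-page HTML+SVG
```

The hippocampal volumes that look unremarkable in mL sit at the 7th and
20th percentiles once age, sex and head size are regressed out — exactly
the contextualisation the report exists to provide.

A full simulated reader study, analysed end to end:

```r
cohort  <- simulate_test_cohort(seed = 7)
ratings <- simulate_raters(cohort, default_rater_specs(), seed = 7)
gold    <- tibble::tibble(scan_id = cohort$subject_id, group = cohort$group)
res     <- analyse_study(ratings, gold)

res$metric_summary %>%
  filter(task == "volume_loss", metric == "sensitivity") %>%
  select(experience, mean_without_report, mean_with_report, p_value, cohens_d)
#>   experience   mean_without_report mean_with_report p_value cohens_d
#> 1 analyst                     73.3             82.2  0.0153     1.31
#> 2 consultant                  71.1             80    0.456      1.03
#> 3 registrar                   76.7             84.4  0.0728     2.86
#> 4 all_combined                73.7             82.2  0.0186     1.41
```

The simulated raters were built with volume-loss sensitivity 0.715
without and 0.822 with the report; one simulated study recovers the
gain (73.7% → 82.2% combined) and the paired t test detects it
(p = 0.019). `res` also carries the McNemar tests, per-rater κ tables
with net changes, correct-sub-diagnosis percentages, α/ICC reliability
and the confidence ANOVA.

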