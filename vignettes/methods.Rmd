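---
title: "Normative volumetry reports and reader-study statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative volumetry reports and reader-study statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qreportr)
```

This vignette is the package's own account of its models, conventions and
numerical choices. It states no empirical result that the test suite or
`scripts/acceptance.R` do not themselves compute.

## The normative model

For each region, `fit_normative_model()` fits a single joint
ordinary-least-squares regression of volume (mL) on age (years), sex
(coded 0 = female, 1 = male) and total intracranial volume (TIV, mL)
across a healthy reference population, and stores the residual standard
deviation with the n − 4 denominator. A patient's volume is standardised
against the covariate-specific prediction, z = (v − βx)/σ, and mapped to
a percentile of the healthy population.

Assumptions worth stating explicitly:

* **Joint adjustment, not sequential.** "Regressing out" the covariates
  is implemented as one multivariable fit; sequential residualisation
  would depend on covariate order and double-count shared variance.
* **Linearity in age.** No spline or quadratic age terms; over the
  reference range (roughly 30–100 years) regional grey-matter decline is
  treated as linear. Nonlinear trajectories, site harmonisation and
  longitudinal modelling are out of scope.
* **Homoscedastic residuals.** One σ per region, independent of age and
  head size.

### CDF variants

The mapping from z to a percentile is selectable, because the residual
distribution of a real reference cohort may be mildly skewed:

| variant | formula | role |
|---|---|---|
| `gaussian` (default) | 100·Φ(z) | exact under the model's own assumptions; deterministic |
| `logistic_approx` | 100/(1 + e^(−1.702z)) | the classical logistic approximation to the normal ogive; differs from Gaussian by < 2 percentile points for \|z\| ≤ 3 (property-tested) |
| `generalised_logistic` | 100·(1 + Q·e^(−Bz))^(−1/ν) | a Richards curve; B (growth rate), ν (asymmetry) and Q (offset) are fitted by Nelder–Mead least squares to the empirical CDF of the pooled standardised residuals, initialised at the logistic approximation (B = 1.702, ν = Q = 1) with log-parameterisation keeping all three positive, which guarantees a strictly increasing percentile map |

Percentiles are clipped to [0.01, 99.99] **for display only** (the rose
plot's radial axis is logarithmic and cannot show 0); calibration tests
use the unclipped values. `volume_percentiles(..., clip = FALSE)`
exposes them.

### Brain parenchymal fraction

BPF = (GM + WM)/TIV already normalises by head size, so its normative
model regresses BPF on age alone: regressing a ratio on its own
denominator would induce a spurious TIV association. BPF percentiles use
the Gaussian CDF.

### Quality metrics

SNR = mean WM intensity / background SD and CNR = |WM − GM| / background
SD are documented conventions (white matter as the signal reference);
the package takes the three summary statistics as given and does not
touch images.

## The report

`rose_radius(p) = (log10(p) + 2)/4` maps the display range [0.01, 100]
onto [0, 1]; the log scale devotes half the radius to percentiles below
1, which is where clinical attention belongs. Traffic-light colour
breakpoints default to 1/5/25 (red/orange/yellow/green), aligning with
conventional percentile alarm levels, and are configurable — the
underlying ordering (green high, red low) is the fixed convention.
Radial gridlines sit at percentiles 1, 5, 25, 50, 100; sectors split the
circle equally in region-map order. The exact region/lobe set is
user-supplied (`default_region_map()` provides bilateral frontal,
temporal + hippocampus, parietal, occipital and subcortical/insular
sectors) because segmentation tools differ in parcellation and no single
set is canonical.

`render_report()` writes SVG-in-HTML rather than PDF: the output is
byte-deterministic for identical input, which makes "same bundle, same
document" a testable property. The demographics panel carries age and
sex only — no identifier, diagnosis, MMSE or duration — mirroring rater
blinding in a reading study; a test scans the document for leaked
fields. Left and right hippocampal percentiles are both emitted rather
than a combined value.

## Reader-study statistics

* **Tasks.** `volume_loss` scores abnormal calls against patient status
  on all 45 scans; `AD_vs_normal` / `FTD_vs_normal` restrict to the
  disease group plus controls (31 and 29 scans). The **strict** default
  requires the correct sub-diagnosis for a true positive; because usage
  differs on how a, say, FTD-called AD scan should score, an
  `abnormal_only` convention is available.
* **Group summaries.** Group mean/SD over raters (n − 1 denominator);
  the all-groups-combined mean is the *unweighted* mean of the three
  group means, so each experience level counts equally regardless of
  group size.
* **Cohen's d** uses the pooled-SD convention
  (m₂ − m₁)/√((s₁² + s₂²)/2), which treats the two conditions
  symmetrically and can be computed from summary statistics alone; the
  SD-of-differences convention is available via `d_method = "diff"`.
* **McNemar** defaults to the exact two-sided binomial when the
  discordant count b + c < 25 (typical at this study size) and the
  continuity-corrected χ² otherwise. At b = c the correction is not
  applied — the uncorrected statistic is already exactly 0, and
  "correcting" it would violate corrected ≤ uncorrected.
* **κ, α, ICC** are implemented from their standard formulas (no
  installed package provides them) and are each verified against
  independent brute-force oracles in the test suite. The ICC is the
  two-way mixed, **consistency** form, ICC(3,1)/(3,k): whether absolute
  agreement was intended in the original analyses cannot be determined,
  and consistency is the form algebraically tied to Cronbach's α
  (α = ICC(3,k), tested to 1e−10 on binary matrices).
* **Confidence ANOVA.** Per-rater cell means in the 2×2×2 within
  (report × scan normality × correctness) × experience design, fitted by
  `stats::aov` with one error stratum per within-factor combination;
  partial η² = SS_effect/(SS_effect + SS_error) uses each effect's own
  stratum error. Sums of squares below 1e−12 of the data's total sum of
  squares are treated as exactly zero, so an all-equal design reports
  every F as 0 rather than 0/0 floating-point noise. Missing cells are
  an error, never imputed.
* **Multiplicity.** No correction by default (reported p values are
  unadjusted, flagged at 0.05); `p.adjust`-style Holm correction can be
  applied by the user downstream.
* **Sample size** iterates the noncentral-t power function
  (`power.t.test`, paired) upward; the normal approximation
  ⌈(z₁₋α/₂ + z₁₋β)²/d²⌉ is exposed for comparison and is never more
  than one rater below the noncentral answer on the tested grid.

## The synthetic generators

The generators *define* the study conditions under which the package is
tested:

* **Normative cohort**: n = 461, age ~ N(70.09, 12.05²) truncated to
  [30, 100], 51.4% female, TIV ~ N(1400, 110²) mL for women and
  N(1550, 120²) for men. The upper truncation bound is deliberately
  loose: the reference sources span roughly ages 30–90, but truncating
  at the empirical maximum would bias the realised mean about 1.3 years
  low, so a generous physiological bound keeps the declared moments
  faithful. Ages use exact inverse-CDF truncated-normal sampling.
* **Region model**: 14 rose regions plus total GM/WM, with means at
  typical adult values (e.g. hippocampus 3.2 mL, total GM 620 mL), age
  slopes near −0.3%/year of the regional mean, near-proportional TIV
  scaling, and residual SDs of 5–10% of the mean.
* **Test cohort**: 15 controls / 16 AD / 14 FTD with the published
  group demographics (ages near 60, group-specific sex ratios, MMSE and
  disease duration; controls carry no duration). Atrophy is
  *multiplicative on the model mean before noise*: 0.80 on
  hippocampal/temporal regions for AD, 0.80 on frontal/insular regions
  for FTD, 0.95 elsewhere — subtle loss befitting young, short-duration
  patients. Controls are drawn from the normative process itself; real
  memory-clinic "controls" may be subtly borderline, which this default
  does not model.
* **Raters**: Bernoulli normality calls from condition-specific
  sensitivity/specificity (defaults 0.715 → 0.822 and 0.785 → 0.723,
  mirroring the published combined rows); sub-diagnosis accuracy given a
  correct abnormal call of 0.80 for AD and 0.55 for FTD scans (the FTD
  pattern being harder to recognise); confidences from an additive cell
  model (base 3, +0.8 if correct, +0.4 for patient scans, +0.2 with the
  report) discretised from a Gaussian with SD 0.8 and clipped to 1–5.
  Raters are mutually independent given the scan truth — real raters
  share correlated perception, so simulated interrater reliabilities are
  not expected to reproduce published α/ICC values.
* **Schedules**: each scan appears exactly twice (once per condition) in
  a permutation keyed on (seed, rater id), so orders are unique per
  rater and reproducible; no minimum separation between a scan's two
  episodes is enforced.

Seeds are combined with string keys through a 31-multiplier polynomial
hash reduced modulo 2³¹ − 1, so per-rater and per-cohort streams are
independent, reproducible and order-invariant.

What passing tests show — and don't. Calibration, monotonicity,
parameter recovery and effect recovery hold under the generator's
assumptions (linear covariate effects, Gaussian noise, independent
raters). They do not certify behaviour under segmentation failures,
scanner effects, non-Gaussian residuals or correlated raters.

## Problem sizes and tolerances in the tests

The suite fits reference cohorts of n = 461 (the study-condition size)
where the size itself matters and n = 40–100 elsewhere; calibration
checks use 2,000 fresh subjects drawn from the fitted model's own
generating process, so their percentiles are uniform by construction and
the per-region Kolmogorov–Smirnov check (p > 0.01) tests only the
implementation. Parameter recovery runs 20 seeds on a single-region
benchmark with known coefficients (200, −0.5, 10, 0.05) and σ = 8; the
mean of the 20 estimates must fall within 3 standard errors *of that
mean* — a sharper bias test than per-seed 3σ bounds, which across
20 × 4 comparisons would fail by chance alone in roughly one run in
five. Oracle-equivalence checks run 100 random small instances per
statistic at 1e−8. The simulated reader study uses 3–5 replicates of the
full 810-episode design and requires the built-in sensitivity gain back
within three binomial standard errors of the pooled estimate.

## Known limitations

* The normative model is cross-sectional and linear; percentiles near
  the age-range boundary extrapolate the linear trend.
* The generalised-logistic fit is a least-squares ECDF fit, not maximum
  likelihood; with small reference cohorts its median can drift a few
  percentile points from 50.
* The rater simulator has no learning, fatigue or anchoring effects and
  no between-rater correlation beyond the shared truth.
* `analyse_study()` omits the confidence ANOVA (returns `NULL`) when a
  rater leaves a confidence cell empty — e.g. a rater who is never
  wrong on normal scans — rather than imputing.
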