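---
title: "Size-specific dosimetry for low-dose chest CT: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-specific dosimetry for low-dose chest CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdose)
```

## The dosimetric model

CT scanners report dose against standardized phantoms: CTDIvol (mGy) is the
mean dose to a 32-cm acrylic cylinder per rotation, and the dose–length
product DLP (mGy·cm) integrates it over the scanned length. Neither refers
to the patient actually scanned. Since automatic tube current modulation
(TCM) adjusts output to patient attenuation, a fixed-phantom reference
misstates individual dose for nearly everyone — by more, proportionally, in
low-dose protocols where every tenth of a mGy matters.

`ctdose` implements the standard size-correction chain per examination:

* **BMI** `= weight / height²` (kg/m²; height taken in cm at the interface
  and converted internally),
* **effective diameter** `Deff = sqrt(A × B)` (cm), the geometric mean of
  the lateral (A) and anteroposterior (B) chest dimensions measured on the
  topogram at mid-scan level,
* **conversion factor** `k(Deff) = a·exp(−b·Deff)`, the AAPM Report 204
  exponential fit; for the 32-cm body phantom `a = 3.704369`,
  `b = 0.03671937`, valid on 8–45 cm,
* **SSDE** `= CTDIvol × k` (mGy),
* **DLPss** `= DLP × k` (mGy·cm), which corrects for size *and* keeps the
  scan-length information SSDE discards,
* **effective dose** `ED = DLP × f` with `f = 0.014` mSv/(mGy·cm) (adult
  chest, AAPM Report 96),
* **topogram contribution** `= 100 × DLP_topo / DLP_scan` (%). The
  denominator is deliberately the diagnostic-scan DLP rather than the
  topogram+scan total: this is the definition under which the published
  low-dose (10.23%) and standard-dose (1.84%) contributions are both
  reproduced from their cohort means, so it is the one the package uses
  throughout.
* **ΔL** `= scan length − topogram length` (mm), kept signed; a negative
  value means the diagnostic range was shortened relative to the plan.

All derived metrics are computed **per examination and then aggregated**.
The order matters: a mean of per-patient products `mean(DLP_i × k_i)` is
not the product of means, and published cohort tables are only reproducible
under per-patient computation.

Two numerical conventions worth stating: `k` evaluation outside the model's
validity range raises a range error rather than extrapolating (an explicit
`clamp` option clamps to the boundary with a warning), and the
below-reference share uses the strict inequality `Deff < reference`, with
the boundary counted as at-or-above. Note that under the Report 204 fit
`k = 1` near 35.7 cm, not at the 32-cm reference itself (`k(32) ≈ 1.14`);
the package therefore never claims `k < 1` above 32 cm.

## Cohort statistics

Sex comparisons follow the convention of dose-audit studies: each group is
screened with a Shapiro–Wilk test at α = 0.05; only if *both* groups pass
is a two-sided two-sample t-test used, otherwise a two-sided Mann–Whitney
U. The source convention names the test pair but not the gate's α or the
both-groups rule; α = 0.05 per group with a conjunctive gate is the
conventional reading, and both are parameters of `compare_sexes()`. The
t-test defaults to Welch (unequal variances) — the safer modern default —
with a `pooled` flag restoring the classical version. A group with zero
spread cannot be screened (Shapiro–Wilk is undefined for constant samples)
and is routed to the rank test. When a cohort contains a single sex the
p-value is reported as `NA`/"unavailable", never 1. No multiple-testing
correction is applied; per-variable p-values are raw.

The standard-dose comparison arm enters as a published summary table
(means, SDs, n = 134) via `standard_ct_reference()`, not as raw
examinations. Protocol ratios (`100 × ldct_mean / standard_mean`) need only
the means; the between-protocol p-values are Welch t-tests computed from
summary statistics, which is exact for the t statistic and the only option
without raw data.

## The synthetic cohort generator

No public exam-level dataset exists for this setting, so the generator is a
first-class module: it emulates the statistical structure the analysis
assumes, making every pipeline stage testable end to end.

**Anthropometrics.** Each variable is a sex-conditional truncated normal
(inverse-CDF sampling), with truncation bounds matching the observed ranges
of published LDCT screening cohorts (weight 52–106 kg, height 152–193 cm,
A 26.47–39.78 cm, B 21.56–31.05 cm, age 31.22–77.92 y) and a male fraction
of 135/221 ≈ 0.61. Weight and the two chest dimensions share a latent
"body size" factor inducing a pairwise correlation of 0.6, so larger
patients are larger in every dimension — which is what makes the TCM
dose–size relation, and the sex differences it produces, emerge
mechanistically rather than by construction.

The sex-specific means (men: A 37.0, B 27.6 cm, i.e. Deff ≈ 31.7 cm;
women: A 30.0, B 22.0 cm, Deff ≈ 26.3 cm) were chosen jointly so that the
sex-pooled means of A (≈34.1), B (≈25.7) and Deff (≈29.6) and the share of
patients below the 32-cm reference (≈70%) all match published LDCT cohort
values simultaneously. The point deserves emphasis: a single unimodal Deff
distribution with mean 29.4 and SD 2.8 would put ~82–87% of patients below
32 cm — a ~70% share is only achievable with the sex-mixture structure, a
broad male component reaching above the reference and a female component
almost entirely below it. The within-sex spreads are then whatever the
marginal SDs leave over. Only marginal calibration is claimed; the true
joint distribution of weight, A and B in clinical cohorts is not.

**TCM model.** Tube output follows
`CTDIvol = baseline × exp(exponent × (Deff − reference)) × ε`, with
`reference = 29.41` cm, `exponent = 0.08`/cm (chosen to span roughly the
observed CTDIvol range across the cohort's Deff range), and ε a unit-mean
log-normal with σ = 0.15 on the log scale representing protocol and
positioning variability. The baseline, 1.27 mGy, is calibrated so the
cohort mean CTDIvol is ≈1.33 mGy after accounting for the convexity of the
exponential over the Deff distribution. The result is clamped to protocol
output limits, deliberately loose defaults (0.3–4.0 mGy): clamping at the
*observed* cohort range would censor the log-linear relation and bias its
recovery. `fit_tcm_exponent()` — OLS of `log(CTDIvol)` on `Deff` — is the
parameter-recovery instrument; with noise off it returns the generating
exponent to numerical precision, and with the default noise its 2-SE
interval covers the truth in ≥90% of seeded cohorts.

**Doses.** Scan DLP is generated as `CTDIvol × length` (length in cm) with
a small multiplicative jitter (σ = 0.02), not sampled independently — this
is what makes the `DLPss/DLP = SSDE/CTDIvol = k` conservation identity and
the sex-difference structure hold mechanistically. One consequence: the
implied cohort mean DLP (≈53 mGy·cm) sits slightly above the published
50.35, because a published mean CTDIvol and mean length do not determine
the mean of their per-patient product. The generator's calibration targets
are the CTDIvol, Deff and k means and the below-reference share, not the
DLP mean. The topogram follows a fixed institutional protocol: CTDIvol
jittering tightly under a 0.14-mGy ceiling, DLP in 4–6 mGy·cm, only its
planned length (mean 386.55, SD 50.19 mm) varying substantially.

**Reproducibility.** Every patient draws from an RNG substream derived
deterministically from the global seed and the patient index, so a cohort
is a pure function of `(seed, config)` and growing `n` appends patients
without reshuffling earlier ones. The caller's RNG state is restored on
exit.

**What passing tests do and do not show.** The generator reproduces the
marginal means, ranges and the dose–size mechanism of a real screening
cohort; it does not reproduce real joint anthropometric structure,
scanner-specific TCM firmware behaviour, multi-level (craniocaudal) size
variation, or measurement error in the chest dimensions. Pipeline
correctness established on synthetic cohorts transfers to real data;
cohort-level *numbers* do so only to the extent the marginals match.

## Screening projections

`cumulative_dose_ledger()` assumes constant per-round parameters — the
published projection's assumption of a steady ~10% topogram contribution —
so row r is exactly r times the per-round values and the ledger is
additive across splits. At 25 rounds with a 10.23% topogram share the
topogram accumulates `25 × 0.1023 ≈ 2.6` diagnostic-scan equivalents
(reported to 1 dp). Round-varying schedules, dose drift, and radiation
risk models (BEIR/ICRP lifetime attributable risk) are out of scope.

## Problem sizes used in the test suite

Stochastic properties are checked at the scale of the emulated cohort:
calibration and conservation at n = 221 (the cohort size the generator
mirrors), exponent-recovery coverage over 100 seeded cohorts, the
normality-gated comparison's type-I error over 1,000 null replicates of
50-per-group samples, and permutation-oracle agreement at 10,000
permutations on samples of ≤25 per group. Tolerances were fixed from the
generator's own sampling variance before the checks were run: ±0.1 mGy on
mean CTDIvol, ±0.5 cm on mean Deff, ±0.03 on mean k, ±6 percentage points
on the below-reference share, and a 99% binomial band on the type-I error
rate.

## Known limitations

* Single mid-scan-level `Deff` per patient, as in all Report 204-based
  SSDE work; craniocaudal anatomical variation is not modelled.
* The water-equivalent-diameter refinement (AAPM 220) and organ-dose
  estimation are out of scope, as are DICOM RDSR parsing (tabular export
  assumed) and DRL percentile benchmarking.
* `ED = DLP × f` is a population-level epidemiological quantity; DLPss is
  the per-patient metric. The two are complementary, not interchangeable.
* The 16-cm head-phantom coefficients are included but chest analyses
  should use the 32-cm body phantom throughout.
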