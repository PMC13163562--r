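# ctdose

Individualized radiation dosimetry for low-dose chest CT (LDCT).

Scanner-reported dose metrics — CTDIvol and the dose–length product (DLP) —
refer to a standardized 32-cm acrylic phantom, not to the patient on the
table. Because automatic tube current modulation adapts tube output to the
patient's attenuation, phantom-referenced metrics misstate the dose for
almost everyone: most screening patients have an effective chest diameter
below 32 cm. `ctdose` implements the size-corrected dose chain used in
clinical dose-audit studies and packages it for LDCT lung-cancer-screening
cohorts, where per-examination doses are so low that the planning topogram
becomes a material fraction of the total exposure.

For each examination with lateral and anteroposterior chest dimensions
`A` and `B` (cm, measured on the topogram at mid-scan level):

- effective diameter `Deff = sqrt(A × B)`
- conversion factor `k(Deff) = a · exp(−b · Deff)` — the AAPM Report 204
  exponential fit for the 32-cm body phantom (`a = 3.704369`,
  `b = 0.03671937`)
- size-specific dose estimate `SSDE = CTDIvol × k` (mGy)
- size-specific dose–length product `DLPss = DLP × k` (mGy·cm)
- effective dose `ED = DLP × f`, `f = 0.014` mSv/(mGy·cm) for the adult
  chest (AAPM Report 96)
- topogram contribution `100 × DLP_topogram / DLP_scan` (%)

On top of the per-exam chain the package provides cohort summaries with
normality-gated sex comparisons (Shapiro–Wilk, then Welch t or
Mann–Whitney U), low-dose vs standard-dose protocol ratios, the
effective-diameter distribution about the phantom reference, cumulative
screening-programme dose ledgers, and a calibrated synthetic cohort
generator (sex-conditional anthropometrics plus a tube-current-modulation
dose–size model) so the whole pipeline is testable without clinical data.

## Worked example

```r
library(ctdose)

exams   <- generate_cohort(sim_config(n = 221, seed = 17))
derived <- derive_exams(exams)

summarize_cohort(derived)   # per-variable mean/sd/min/max + sex tests
#   variable         mean     sd    min    max p_sex  test
#   deff_cm         29.24   3.04  24.19  34.70 <0.001 mann_whitney
#   k                1.27   0.14   1.04   1.52 <0.001 mann_whitney
#   scan_ctdivol_mgy 1.29   0.35   0.71   2.27 <0.001 mann_whitney
#   scan_dlp_mgycm  51.65  15.04  25.57 103.22 <0.001 mann_whitney
#   dlpss_mgycm     64.09  13.29  37.22 109.00 <0.001 mann_whitney
```

The synthetic cohort mirrors an LDCT screening population: mean CTDIvol
1.29 mGy, mean effective diameter 29.2 cm, mean k 1.27, and DLPss
exceeding DLP by roughly the size correction (64.1 vs 51.6 mGy·cm).

```r
deff_distribution(derived$deff_cm)
#   reference_cm   n pct_below pct_at_or_above
#             32 221      75.1            24.9

compare_protocols(summarize_cohort(derived))   # vs published standard-CT arm
#   variable         ldct_mean standard_mean ratio_pct_display
#   scan_ctdivol_mgy      1.29          7.83              16.5
#   ssde_mgy              1.61          9.37              17.1
#   scan_dlp_mgycm       51.65        286.51              18.0
#   dlpss_mgycm          64.09        343.90              18.6
```

Three quarters of patients sit below the 32-cm phantom reference, and the
low-dose protocol delivers 16–19% of the standard-dose values — a dose
reduction exceeding 80% for every metric.

```r
sc <- screening_scenario(25, scan_dlp = 50.35, topogram_dlp = 5.15)
tail(cumulative_dose_ledger(sc), 1)
#   round cum_total_dlp_mgycm cum_scan_ed_msv cum_topo_scan_equivalents
#      25              1387.5         17.6225                    2.5571

cumulative_topogram_equivalents(25, 10.23)  # 2.5575 -> "2.6 scans"
```

Over a 25-round screening programme the topogram alone accumulates the
dose of about 2.6 extra diagnostic scans — the case for optimizing the
topogram, not just the diagnostic acquisition.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/ctdose.R simulate --n 221 --seed 17 --out exams.csv
Rscript inst/cli/ctdose.R analyze  --input exams.csv --out results/
Rscript inst/cli/ctdose.R project  --rounds 25 --topogram-fraction 10.23 \
    --scan-dlp 50.35 --out ledger.csv
```

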