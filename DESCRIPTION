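Package: ctdose
Title: Size-Specific Radiation Dosimetry for Low-Dose Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individualized radiation dose assessment for low-dose chest CT
    (LDCT) examinations. Computes per-examination size-specific dose metrics
    from scanner dose reports and topogram-measured chest dimensions: body
    mass index, effective diameter, the AAPM Report 204 size-dependent
    conversion factor k, the size-specific dose estimate (SSDE), the
    size-specific dose-length product (DLPss), and effective dose. Aggregates
    examinations into cohort summaries with normality-gated sex comparisons,
    compares low-dose against standard-dose protocols, quantifies the
    topogram's contribution to examination dose, and projects cumulative
    exposure over longitudinal screening programmes. A calibrated synthetic
    cohort generator with a tube-current-modulation dose-size model makes the
    whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
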