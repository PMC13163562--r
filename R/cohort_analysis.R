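#' Normality-gated two-sample sex comparison
#'
#' Compares a continuous variable between female and male patients the way
#' dose-audit studies usually do: each group is screened with the
#' Shapiro-Wilk test; if both groups look normal at the chosen significance
#' level, a two-sided two-sample t-test is used (Welch by default), otherwise
#' a two-sided Mann-Whitney U (Wilcoxon rank-sum) test.
#'
#' A group with zero spread can never pass a normality screen, so it is
#' routed to the rank-based test directly (Shapiro-Wilk is undefined for
#' constant samples).
#'
#' @param values_f,values_m Numeric vectors for the two groups; each needs at
#'   least 3 observations.
#' @param alpha Significance level of the Shapiro-Wilk normality gate.
#' @param pooled Use the pooled-variance (classical Student) t-test instead
#'   of the Welch default when the gate selects the t-test.
#'
#' @return A list with elements `p_value`, `test` (`"t_test"` or
#'   `"mann_whitney"`), and `statistic`.
#' @examples
#' compare_sexes(rnorm(20), rnorm(20, 1))
#' @export
compare_sexes <- function(values_f, values_m, alpha = 0.05, pooled = FALSE) {
  values_f <- values_f[is.finite(values_f)]
  values_m <- values_m[is.finite(values_m)]
  if (length(values_f) < 3 || length(values_m) < 3) {
    abort_insufficient(
      "Each group needs at least 3 finite observations for a sex comparison."
    )
  }
  normal <- function(x) {
    if (sd(x) == 0 || length(x) > 5000) return(FALSE)
    shapiro.test(x)$p.value > alpha
  }
  if (normal(values_f) && normal(values_m)) {
    ht <- t.test(values_f, values_m, var.equal = pooled)
    list(p_value = unname(ht$p.value), test = "t_test",
         statistic = unname(ht$statistic))
  } else {
    ht <- suppressWarnings(wilcox.test(values_f, values_m))
    list(p_value = unname(ht$p.value), test = "mann_whitney",
         statistic = unname(ht$statistic))
  }
}

#' Variables summarized in a cohort report
#'
#' Default set of anthropometric and dosimetric variables summarized by
#' [summarize_cohort()], in report order.
#'
#' @return Character vector of column names of a derived examination table.
#' @export
cohort_variables <- function() {
  c("age_years", "weight_kg", "height_cm", "bmi_kg_m2",
    "lat_dim_a_cm", "ap_dim_b_cm", "deff_cm", "k",
    "topo_length_mm", "topo_ctdivol_mgy", "topo_dlp_mgycm",
    "scan_length_mm", "scan_ctdivol_mgy", "ssde_mgy",
    "scan_dlp_mgycm", "dlpss_mgycm",
    "effective_dose_msv", "topogram_fraction_pct", "delta_length_mm")
}

#' Cohort summary statistics with sex comparisons
#'
#' Per-variable mean, sample standard deviation (n - 1 denominator), minimum
#' and maximum over all examinations, plus a sex-comparison p-value from
#' [compare_sexes()] where both sexes contribute at least 3 observations.
#' When only one sex is present the p-value is `NA` and the test is marked
#' `"unavailable"` (a p of 1 would wrongly claim evidence of no difference).
#'
#' @param derived A derived examination table from [derive_exams()].
#' @param variables Columns to summarize; defaults to [cohort_variables()]
#'   (restricted to those present).
#'
#' @return A tibble with one row per variable: `variable`, `n`, `mean`, `sd`,
#'   `min`, `max`, `p_sex`, `test`.
#' @export
summarize_cohort <- function(derived, variables = cohort_variables()) {
  if (!is.data.frame(derived) || nrow(derived) == 0) {
    abort_empty("Cannot summarize an empty cohort.")
  }
  if (nrow(derived) < 2) {
    abort_insufficient("Cohort summaries need at least 2 examinations.")
  }
  variables <- intersect(variables, names(derived))
  if (length(variables) == 0) {
    abort_schema("None of the requested variables are present.")
  }
  has_sex <- "sex" %in% names(derived)
  rows <- lapply(variables, function(v) {
    x <- derived[[v]]
    p <- NA_real_
    test <- "unavailable"
    if (has_sex) {
      xf <- x[derived$sex == "F"]
      xm <- x[derived$sex == "M"]
      if (length(xf) >= 3 && length(xm) >= 3) {
        cmp <- compare_sexes(xf, xm)
        p <- cmp$p_value
        test <- cmp$test
      }
    }
    tibble::tibble(variable = v, n = length(x), mean = mean(x), sd = sd(x),
                   min = min(x), max = max(x), p_sex = p, test = test)
  })
  dplyr::bind_rows(rows)
}

#' Distribution of effective diameters about a reference phantom diameter
#'
#' Share of patients whose effective diameter lies strictly below the
#' reference phantom diameter (32 cm for the chest) versus at or above it.
#' Patients below the reference diameter receive a larger size correction
#' (`k` grows as the effective diameter shrinks), so this split shows how
#' much of a cohort the phantom-referenced metrics misrepresent.
#'
#' @param deff_cm Numeric vector of effective diameters, cm.
#' @param reference_cm Reference phantom diameter, cm (default 32).
#' @return A tibble with `reference_cm`, `n`, `pct_below`,
#'   `pct_at_or_above` (percentages summing to 100).
#' @export
deff_distribution <- function(deff_cm, reference_cm = 32) {
  if (length(deff_cm) == 0) {
    abort_empty("`deff_cm` must contain at least one value.")
  }
  check_positive(deff_cm, "deff_cm")
  check_positive(reference_cm, "reference_cm")
  pct_below <- 100 * mean(deff_cm < reference_cm)
  tibble::tibble(
    reference_cm = reference_cm,
    n = length(deff_cm),
    pct_below = pct_below,
    pct_at_or_above = 100 - pct_below
  )
}
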