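#' Published standard-dose chest CT reference summary
#'
#' Cohort-level dose statistics of a standard-dose chest CT companion cohort
#' (n = 134) used as the comparison arm for low-dose protocols. These are
#' summary statistics (mean, SD), not raw examinations.
#'
#' @return A tibble with columns `variable`, `n`, `mean`, `sd`.
#' @export
standard_ct_reference <- function() {
  tibble::tibble(
    variable = c("scan_ctdivol_mgy", "ssde_mgy", "scan_dlp_mgycm",
                 "dlpss_mgycm", "topo_dlp_mgycm", "topogram_fraction_pct",
                 "effective_dose_msv"),
    n = 134L,
    mean = c(7.83, 9.37, 286.51, 343.90, 5.28, 1.84, 4.01),
    sd = c(2.92, 2.31, 99.82, 81.66, 0.60, NA_real_, 1.40)
  )
}

#' Dose parameters compared across protocols
#' @return Character vector of the dose-parameter variable names compared by
#'   [compare_protocols()] by default.
#' @export
protocol_dose_parameters <- function() {
  c("scan_ctdivol_mgy", "ssde_mgy", "scan_dlp_mgycm", "dlpss_mgycm",
    "topo_dlp_mgycm")
}

# Welch two-sample t-test from summary statistics only.
welch_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (any(!is.finite(c(m1, s1, n1, m2, s2, n2))) || n1 < 2 || n2 < 2) {
    return(NA_real_)
  }
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  t_stat <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  2 * pt(-abs(t_stat), df)
}

#' Compare low-dose against standard-dose protocol summaries
#'
#' For each dose parameter, expresses the low-dose cohort mean as a
#' percentage of the standard-dose mean (`ratio_pct = 100 * ldct / standard`)
#' and the complementary dose reduction (`100 - ratio_pct`). Where both
#' summaries carry an SD and n, a Welch t-test computed from the summary
#' statistics provides an approximate between-protocol p-value.
#'
#' @param ldct Cohort summary of the low-dose protocol (from
#'   [summarize_cohort()], or any tibble with `variable`, `mean` and
#'   optionally `sd`, `n`).
#' @param standard Cohort summary of the standard-dose protocol, same shape;
#'   defaults to the published reference cohort [standard_ct_reference()].
#' @param parameters Dose parameters to compare; all must be present in both
#'   summaries.
#'
#' @return A tibble with one row per parameter: `variable`, `ldct_mean`,
#'   `standard_mean`, `ratio_pct` (full precision), `ratio_pct_display`
#'   (rounded to 1 dp), `dose_reduction_pct`, `p_value`.
#' @examples
#' ldct <- summarize_cohort(derive_exams(generate_cohort(sim_config(seed = 1))))
#' compare_protocols(ldct)
#' @export
compare_protocols <- function(ldct, standard = standard_ct_reference(),
                              parameters = protocol_dose_parameters()) {
  for (nm in c("ldct", "standard")) {
    tab <- get(nm)
    if (!is.data.frame(tab) || !all(c("variable", "mean") %in% names(tab))) {
      abort_schema(sprintf("`%s` must have columns `variable` and `mean`.", nm))
    }
    missing <- setdiff(parameters, tab$variable)
    if (length(missing) > 0) {
      abort_schema(sprintf("`%s` is missing dose parameter(s): %s.",
                           nm, paste(missing, collapse = ", ")))
    }
  }
  pick <- function(tab, col) {
    if (col %in% names(tab)) tab[[col]][match(parameters, tab$variable)]
    else rep(NA_real_, length(parameters))
  }
  l_mean <- pick(ldct, "mean")
  s_mean <- pick(standard, "mean")
  if (any(!is.finite(s_mean) | s_mean <= 0)) {
    abort_invalid("Standard-protocol means must be positive to form ratios.")
  }
  ratio <- 100 * l_mean / s_mean
  p <- mapply(welch_from_summary,
              l_mean, pick(ldct, "sd"), pick(ldct, "n"),
              s_mean, pick(standard, "sd"), pick(standard, "n"))
  tibble::tibble(
    variable = parameters,
    ldct_mean = l_mean,
    standard_mean = s_mean,
    ratio_pct = ratio,
    ratio_pct_display = round(ratio, 1),
    dose_reduction_pct = 100 - ratio,
    p_value = as.numeric(p)
  )
}
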