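#' Effective-dose conversion coefficients
#'
#' The effective dose of a chest CT examination is estimated from the
#' dose-length product with the fixed anatomical coefficient
#' \eqn{f = 0.014} mSv/(mGy cm) for the adult chest (AAPM Report 96).
#'
#' @param ed_conversion_f Conversion coefficient, mSv per mGy·cm; > 0.
#' @return An object of class `dose_coefficients`.
#' @export
dose_coefficients <- function(ed_conversion_f = 0.014) {
  check_positive(ed_conversion_f, "ed_conversion_f")
  structure(list(ed_conversion_f = ed_conversion_f),
            class = "dose_coefficients")
}

#' Body mass index
#'
#' @param weight_kg Body weight, kg.
#' @param height_cm Body height, cm (converted to metres internally).
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(100, 200)
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  check_positive(weight_kg, "weight_kg")
  check_positive(height_cm, "height_cm")
  weight_kg / (height_cm / 100)^2
}

#' Effective diameter of the chest
#'
#' Geometric mean of the lateral (A) and anteroposterior (B) chest dimensions
#' measured on the topogram at the mid-scan level:
#' \eqn{D_{eff} = \sqrt{A \times B}} (cm). Symmetric in its arguments.
#'
#' @param lat_dim_a_cm Lateral chest dimension A, cm.
#' @param ap_dim_b_cm Anteroposterior chest dimension B, cm.
#' @return Effective diameter, cm.
#' @examples
#' compute_effective_diameter(34.06, 25.43)
#' @export
compute_effective_diameter <- function(lat_dim_a_cm, ap_dim_b_cm) {
  check_positive(lat_dim_a_cm, "lat_dim_a_cm")
  check_positive(ap_dim_b_cm, "ap_dim_b_cm")
  sqrt(lat_dim_a_cm * ap_dim_b_cm)
}

#' Size-specific dose estimate (SSDE)
#'
#' \eqn{SSDE = CTDIvol \times k}.
#'
#' @param ctdi_vol Volume CT dose index, mGy; >= 0.
#' @param k Size-specific conversion factor, dimensionless; > 0.
#' @return SSDE, mGy.
#' @export
compute_ssde <- function(ctdi_vol, k) {
  check_non_negative(ctdi_vol, "ctdi_vol")
  check_positive(k, "k")
  ctdi_vol * k
}

#' Size-specific dose-length product (DLPss)
#'
#' \eqn{DLP_{ss} = DLP \times k}: the dose-length product rescaled by the
#' same size-specific factor as SSDE, so it carries both the patient's size
#' and the actual scanned length.
#'
#' @param dlp Dose-length product, mGy·cm; >= 0.
#' @param k Size-specific conversion factor, dimensionless; > 0.
#' @return DLPss, mGy·cm.
#' @export
compute_dlpss <- function(dlp, k) {
  check_non_negative(dlp, "dlp")
  check_positive(k, "k")
  dlp * k
}

#' Effective dose from the dose-length product
#'
#' \eqn{ED = DLP \times f} with the anatomical conversion coefficient from
#' [dose_coefficients()].
#'
#' @param dlp Dose-length product, mGy·cm; >= 0.
#' @param coeffs A [dose_coefficients()] object.
#' @return Effective dose, mSv.
#' @examples
#' compute_effective_dose(50.35)
#' @export
compute_effective_dose <- function(dlp, coeffs = dose_coefficients()) {
  check_non_negative(dlp, "dlp")
  if (!inherits(coeffs, "dose_coefficients")) {
    abort_invalid("`coeffs` must be a `dose_coefficients` object.")
  }
  dlp * coeffs$ed_conversion_f
}

#' Topogram contribution to examination dose
#'
#' Percentage of the diagnostic-scan DLP contributed by the topogram
#' (scout/localizer) acquisition: `100 * topogram_dlp / scan_dlp`. The
#' denominator is the diagnostic-scan DLP, not the topogram+scan total.
#'
#' @param topogram_dlp Topogram DLP, mGy·cm; >= 0.
#' @param scan_dlp Diagnostic-scan DLP, mGy·cm; > 0.
#' @return Contribution in percent.
#' @examples
#' topogram_contribution(5.15, 50.35)
#' @export
topogram_contribution <- function(topogram_dlp, scan_dlp) {
  check_non_negative(topogram_dlp, "topogram_dlp")
  check_positive(scan_dlp, "scan_dlp")
  100 * topogram_dlp / scan_dlp
}

#' Derive all per-examination dose metrics
#'
#' Takes an examination table (one row per examination, columns as in
#' [exam_table_schema()]) and appends every derived metric: BMI, effective
#' diameter, conversion factor k, SSDE, DLPss, effective dose, the topogram's
#' percentage contribution, and the signed difference between diagnostic-scan
#' and topogram length. All metrics are computed per examination; cohort
#' summaries average the derived values, never the other way round.
#'
#' @param exams A data frame following [exam_table_schema()].
#' @param model A [k_factor_model()].
#' @param coeffs A [dose_coefficients()] object.
#' @param clamp_deff Clamp out-of-range effective diameters to the model
#'   boundary instead of raising an error (logged as a warning).
#'
#' @return The input tibble with columns `bmi_kg_m2`, `deff_cm`, `k`,
#'   `ssde_mgy`, `dlpss_mgycm`, `effective_dose_msv`,
#'   `topogram_fraction_pct`, and `delta_length_mm` appended.
#' @examples
#' exams <- generate_cohort(sim_config(n = 5, seed = 1))
#' derive_exams(exams)
#' @export
derive_exams <- function(exams, model = k_factor_model(),
                         coeffs = dose_coefficients(), clamp_deff = FALSE) {
  check_exam_table(exams)
  deff <- compute_effective_diameter(exams$lat_dim_a_cm, exams$ap_dim_b_cm)
  lo <- model$deff_range[1]
  hi <- model$deff_range[2]
  bad <- deff < lo | deff > hi
  if (any(bad) && !clamp_deff) {
    abort_range(sprintf(
      "Effective diameter outside [%g, %g] cm for patient(s): %s.",
      lo, hi, paste(exams$patient_id[bad], collapse = ", ")
    ))
  }
  k <- k_factor(deff, model, clamp = clamp_deff)
  dplyr::mutate(
    tibble::as_tibble(exams),
    bmi_kg_m2 = compute_bmi(.data$weight_kg, .data$height_cm),
    deff_cm = deff,
    k = k,
    ssde_mgy = compute_ssde(.data$scan_ctdivol_mgy, k),
    dlpss_mgycm = compute_dlpss(.data$scan_dlp_mgycm, k),
    effective_dose_msv = compute_effective_dose(.data$scan_dlp_mgycm, coeffs),
    topogram_fraction_pct = topogram_contribution(.data$topo_dlp_mgycm,
                                                  .data$scan_dlp_mgycm),
    delta_length_mm = .data$scan_length_mm - .data$topo_length_mm
  )
}
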