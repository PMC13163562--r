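#' Cumulative topogram dose in units of diagnostic scans
#'
#' Over a screening programme of `n_rounds` examinations whose topogram
#' contributes `topogram_fraction` percent of the diagnostic-scan dose each
#' round, the accumulated topogram dose equals
#' `n_rounds * topogram_fraction / 100` full diagnostic scans.
#'
#' @param n_rounds Number of screening examinations; >= 0.
#' @param topogram_fraction Topogram contribution per round, percent; >= 0.
#' @return Cumulative topogram dose in diagnostic-scan equivalents
#'   (dimensionless).
#' @examples
#' cumulative_topogram_equivalents(25, 10.23)
#' @export
cumulative_topogram_equivalents <- function(n_rounds, topogram_fraction) {
  if (any(!is.finite(n_rounds)) || any(n_rounds < 0)) {
    abort_invalid("`n_rounds` must be a non-negative, finite count.")
  }
  check_non_negative(topogram_fraction, "topogram_fraction")
  n_rounds * topogram_fraction / 100
}

#' Screening-programme scenario
#'
#' Per-round dose parameters of a longitudinal screening programme. The
#' topogram is parameterized either by its explicit per-round DLP or by its
#' percentage contribution to the diagnostic-scan DLP — exactly one of the
#' two. Per-round parameters are constant across rounds.
#'
#' @param n_rounds Number of screening rounds; >= 0.
#' @param scan_dlp Diagnostic-scan DLP per round, mGy·cm.
#' @param topogram_dlp Topogram DLP per round, mGy·cm (explicit
#'   parameterization).
#' @param topogram_fraction Topogram contribution per round as a percentage
#'   of `scan_dlp` (alternative parameterization).
#' @param scan_dlpss Optional size-specific DLP per round, mGy·cm; adds a
#'   cumulative DLPss column to the ledger.
#' @return An object of class `screening_scenario`.
#' @export
screening_scenario <- function(n_rounds, scan_dlp, topogram_dlp = NULL,
                               topogram_fraction = NULL, scan_dlpss = NULL) {
  if (length(n_rounds) != 1 || !is.finite(n_rounds) || n_rounds < 0 ||
      n_rounds != round(n_rounds)) {
    abort_invalid("`n_rounds` must be a single non-negative integer.")
  }
  check_non_negative(scan_dlp, "scan_dlp")
  if (is.null(topogram_dlp) == is.null(topogram_fraction)) {
    abort_invalid(
      "Supply exactly one of `topogram_dlp` or `topogram_fraction`."
    )
  }
  if (is.null(topogram_dlp)) {
    check_non_negative(topogram_fraction, "topogram_fraction")
    topogram_dlp <- scan_dlp * topogram_fraction / 100
  } else {
    check_non_negative(topogram_dlp, "topogram_dlp")
    topogram_fraction <- if (scan_dlp > 0) 100 * topogram_dlp / scan_dlp
                         else NA_real_
  }
  if (!is.null(scan_dlpss)) check_non_negative(scan_dlpss, "scan_dlpss")
  structure(
    list(n_rounds = as.integer(n_rounds), scan_dlp = scan_dlp,
         topogram_dlp = topogram_dlp, topogram_fraction = topogram_fraction,
         scan_dlpss = scan_dlpss),
    class = "screening_scenario"
  )
}

#' Cumulative dose ledger for a screening programme
#'
#' Round-by-round cumulative dose table: each row r holds r times the
#' per-round values, so every cumulative column is non-decreasing in the
#' round number.
#'
#' @param scenario A [screening_scenario()].
#' @param coeffs A [dose_coefficients()] object for the effective-dose
#'   columns.
#' @return A tibble with one row per round: per-round DLPs, cumulative scan,
#'   topogram and total DLP (mGy·cm), cumulative scan and total effective
#'   dose (mSv), cumulative topogram dose in diagnostic-scan equivalents,
#'   and — when the scenario carries a per-round DLPss — cumulative DLPss.
#' @examples
#' sc <- screening_scenario(25, scan_dlp = 50.35, topogram_dlp = 5.15)
#' tail(cumulative_dose_ledger(sc), 1)
#' @export
cumulative_dose_ledger <- function(scenario, coeffs = dose_coefficients()) {
  if (!inherits(scenario, "screening_scenario")) {
    abort_invalid("`scenario` must be a `screening_scenario` object.")
  }
  n <- scenario$n_rounds
  if (n == 0) {
    rounds <- integer(0)
  } else {
    rounds <- seq_len(n)
  }
  f <- coeffs$ed_conversion_f
  ledger <- tibble::tibble(
    round = rounds,
    scan_dlp_mgycm = rep(scenario$scan_dlp, n),
    topo_dlp_mgycm = rep(scenario$topogram_dlp, n),
    cum_scan_dlp_mgycm = rounds * scenario$scan_dlp,
    cum_topo_dlp_mgycm = rounds * scenario$topogram_dlp,
    cum_total_dlp_mgycm = rounds * (scenario$scan_dlp + scenario$topogram_dlp),
    cum_scan_ed_msv = rounds * scenario$scan_dlp * f,
    cum_total_ed_msv = rounds * (scenario$scan_dlp + scenario$topogram_dlp) * f,
    cum_topo_scan_equivalents =
      cumulative_topogram_equivalents(rounds, scenario$topogram_fraction)
  )
  if (!is.null(scenario$scan_dlpss)) {
    ledger$cum_scan_dlpss_mgycm <- rounds * scenario$scan_dlpss
  }
  ledger
}
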