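#' Sex-conditional anthropometric profile of a screening cohort
#'
#' Distributional parameters used by [generate_cohort()] to sample patient
#' anthropometrics. Each variable is a sex-conditional truncated normal;
#' weight and the two chest dimensions additionally share a latent "body
#' size" factor so that larger patients are larger in every dimension
#' (pairwise correlation `latent_correlation`).
#'
#' The default profile emulates an adult LDCT lung-screening cohort:
#' roughly 61% men, men systematically taller, heavier and broader-chested
#' than women, with truncation bounds matching the observed ranges of such
#' cohorts. Sex-specific means are chosen so the sex-pooled means and the
#' share of patients below the 32-cm reference diameter match published
#' LDCT cohort values.
#'
#' @param male_fraction Proportion of male patients, in (0, 1).
#' @param latent_correlation Pairwise correlation induced among weight and
#'   the chest dimensions by the shared size factor, in \[0, 1).
#' @param male,female Per-sex parameter lists; each entry is `c(mean, sd)`
#'   for `age` (years), `weight` (kg), `height` (cm), `lat_dim_a` (cm),
#'   `ap_dim_b` (cm).
#' @param bounds Truncation bounds, `c(min, max)` per variable.
#' @return An object of class `anthropometric_profile`.
#' @export
anthropometric_profile <- function(
    male_fraction = 135 / 221,
    latent_correlation = 0.6,
    male = list(age = c(57.5, 14.5), weight = c(80.0, 13.0),
                height = c(175.0, 7.0), lat_dim_a = c(37.0, 2.3),
                ap_dim_b = c(27.6, 2.0)),
    female = list(age = c(60.0, 15.5), weight = c(61.5, 9.0),
                  height = c(158.0, 6.0), lat_dim_a = c(30.0, 2.0),
                  ap_dim_b = c(22.0, 1.6)),
    bounds = list(age = c(31.22, 77.92), weight = c(52, 106),
                  height = c(152, 193), lat_dim_a = c(26.47, 39.78),
                  ap_dim_b = c(21.56, 31.05))) {
  problems <- character()
  if (!is.finite(male_fraction) || male_fraction <= 0 || male_fraction >= 1) {
    problems <- c(problems, "`male_fraction` must lie in (0, 1)")
  }
  if (!is.finite(latent_correlation) || latent_correlation < 0 ||
      latent_correlation >= 1) {
    problems <- c(problems, "`latent_correlation` must lie in [0, 1)")
  }
  vars <- c("age", "weight", "height", "lat_dim_a", "ap_dim_b")
  for (sex in list(male = male, female = female)) {
    for (v in vars) {
      par <- sex[[v]]
      if (is.null(par) || length(par) != 2 || !all(is.finite(par)) ||
          par[2] <= 0) {
        problems <- c(problems,
                      sprintf("`%s` needs c(mean, sd) with sd > 0", v))
      }
    }
  }
  for (v in vars) {
    b <- bounds[[v]]
    if (is.null(b) || length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2]) {
      problems <- c(problems, sprintf("bounds for `%s` must be increasing", v))
    }
  }
  if (length(problems) > 0) {
    abort_config(paste0("Invalid anthropometric profile:\n",
                        paste("-", unique(problems), collapse = "\n")))
  }
  structure(list(male_fraction = male_fraction,
                 latent_correlation = latent_correlation,
                 male = male, female = female, bounds = bounds),
            class = "anthropometric_profile")
}

#' Tube-current-modulation dose-size model
#'
#' Automatic tube current modulation adapts tube output to patient
#' attenuation, so CTDIvol rises roughly exponentially with effective
#' diameter. The generator realizes this as
#' \deqn{CTDIvol = baseline \cdot e^{\,exponent\,(D_{eff} - reference)} \cdot
#'   \varepsilon,}
#' with \eqn{\varepsilon} multiplicative log-normal noise of unit mean, then
#' clamps the result to the scanner's protocol output limits
#' `[ctdi_floor, ctdi_cap]`.
#'
#' @param baseline_ctdi CTDIvol at the reference diameter, mGy.
#' @param size_exponent Exponential growth rate per cm of effective diameter.
#' @param reference_deff Effective diameter at which the baseline applies, cm.
#' @param lognormal_noise_sd SD of the log-normal noise on the log scale;
#'   0 gives a noise-free deterministic dose-size relation.
#' @param ctdi_floor,ctdi_cap Protocol output limits, mGy. The defaults are
#'   deliberately loose so clamping is a rare tail event and the log-linear
#'   dose-size relation stays estimable.
#' @return An object of class `tcm_model`.
#' @export
tcm_model <- function(baseline_ctdi = 1.27, size_exponent = 0.08,
                      reference_deff = 29.41, lognormal_noise_sd = 0.15,
                      ctdi_floor = 0.3, ctdi_cap = 4.0) {
  problems <- character()
  if (!is.finite(baseline_ctdi) || baseline_ctdi <= 0) {
    problems <- c(problems, "`baseline_ctdi` must be > 0")
  }
  if (!is.finite(size_exponent) || size_exponent < 0) {
    problems <- c(problems, "`size_exponent` must be >= 0")
  }
  if (!is.finite(reference_deff) || reference_deff <= 0) {
    problems <- c(problems, "`reference_deff` must be > 0")
  }
  if (!is.finite(lognormal_noise_sd) || lognormal_noise_sd < 0) {
    problems <- c(problems, "`lognormal_noise_sd` must be >= 0")
  }
  if (!is.finite(ctdi_floor) || !is.finite(ctdi_cap) || ctdi_floor <= 0 ||
      ctdi_cap <= ctdi_floor) {
    problems <- c(problems, "need 0 < ctdi_floor < ctdi_cap")
  }
  if (length(problems) > 0) {
    abort_config(paste0("Invalid TCM model:\n",
                        paste("-", problems, collapse = "\n")))
  }
  structure(list(baseline_ctdi = baseline_ctdi,
                 size_exponent = size_exponent,
                 reference_deff = reference_deff,
                 lognormal_noise_sd = lognormal_noise_sd,
                 ctdi_floor = ctdi_floor, ctdi_cap = ctdi_cap),
            class = "tcm_model")
}

#' Fixed-parameter topogram protocol
#'
#' The topogram (scout) is acquired with standardized parameters applied
#' uniformly regardless of body habitus, so its dose metrics are near-fixed:
#' CTDIvol jitters tightly under a protocol ceiling, the DLP varies in a
#' narrow band, and only the planned length varies patient to patient.
#'
#' @param ctdi_mean,ctdi_sd,ctdi_bounds Topogram CTDIvol distribution, mGy.
#' @param dlp_mean,dlp_sd,dlp_bounds Topogram DLP distribution, mGy·cm.
#' @param length_mean,length_sd,length_bounds Topogram length, mm.
#' @return An object of class `topogram_protocol`.
#' @export
topogram_protocol <- function(ctdi_mean = 0.138, ctdi_sd = 0.012,
                              ctdi_bounds = c(0.10, 0.14),
                              dlp_mean = 5.15, dlp_sd = 0.59,
                              dlp_bounds = c(4.0, 6.0),
                              length_mean = 386.55, length_sd = 50.19,
                              length_bounds = c(297, 512)) {
  problems <- character()
  trip <- list(ctdi = list(ctdi_mean, ctdi_sd, ctdi_bounds),
               dlp = list(dlp_mean, dlp_sd, dlp_bounds),
               length = list(length_mean, length_sd, length_bounds))
  for (v in names(trip)) {
    t <- trip[[v]]
    if (!is.finite(t[[1]]) || t[[1]] <= 0 || !is.finite(t[[2]]) ||
        t[[2]] < 0 || length(t[[3]]) != 2 || !all(is.finite(t[[3]])) ||
        t[[3]][1] <= 0 || t[[3]][1] >= t[[3]][2]) {
      problems <- c(problems, sprintf("invalid topogram `%s` parameters", v))
    }
  }
  if (length(problems) > 0) {
    abort_config(paste0("Invalid topogram protocol:\n",
                        paste("-", problems, collapse = "\n")))
  }
  structure(list(ctdi_mean = ctdi_mean, ctdi_sd = ctdi_sd,
                 ctdi_bounds = ctdi_bounds, dlp_mean = dlp_mean,
                 dlp_sd = dlp_sd, dlp_bounds = dlp_bounds,
                 length_mean = length_mean, length_sd = length_sd,
                 length_bounds = length_bounds),
            class = "topogram_protocol")
}

#' Simulation configuration for a synthetic LDCT cohort
#'
#' @param n Number of examinations to generate; >= 1.
#' @param seed Integer seed; the generator gives every patient an independent
#'   substream derived from it, so cohorts are reproducible and growing `n`
#'   extends a cohort without reshuffling earlier patients.
#' @param profile An [anthropometric_profile()].
#' @param tcm A [tcm_model()].
#' @param topogram A [topogram_protocol()].
#' @param scan_length_mean,scan_length_sd,scan_length_bounds Diagnostic-scan
#'   length distribution, mm (truncated normal).
#' @param dlp_jitter_sd Log-scale SD of the multiplicative jitter between
#'   `CTDIvol * length` and the reported scan DLP.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 221, seed = 17,
                       profile = anthropometric_profile(),
                       tcm = tcm_model(),
                       topogram = topogram_protocol(),
                       scan_length_mean = 403.00, scan_length_sd = 29.84,
                       scan_length_bounds = c(341, 445),
                       dlp_jitter_sd = 0.02) {
  problems <- character()
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n)) {
    problems <- c(problems, "`n` must be a positive integer")
  }
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed)) {
    problems <- c(problems, "`seed` must be an integer")
  }
  if (!inherits(profile, "anthropometric_profile")) {
    problems <- c(problems, "`profile` must be an anthropometric_profile")
  }
  if (!inherits(tcm, "tcm_model")) {
    problems <- c(problems, "`tcm` must be a tcm_model")
  }
  if (!inherits(topogram, "topogram_protocol")) {
    problems <- c(problems, "`topogram` must be a topogram_protocol")
  }
  if (!is.finite(scan_length_mean) || scan_length_mean <= 0 ||
      !is.finite(scan_length_sd) || scan_length_sd < 0 ||
      length(scan_length_bounds) != 2 ||
      scan_length_bounds[1] >= scan_length_bounds[2]) {
    problems <- c(problems, "invalid scan-length parameters")
  }
  if (!is.finite(dlp_jitter_sd) || dlp_jitter_sd < 0) {
    problems <- c(problems, "`dlp_jitter_sd` must be >= 0")
  }
  if (length(problems) > 0) {
    abort_config(paste0("Invalid simulation configuration:\n",
                        paste("-", problems, collapse = "\n")))
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 profile = profile, tcm = tcm, topogram = topogram,
                 scan_length_mean = scan_length_mean,
                 scan_length_sd = scan_length_sd,
                 scan_length_bounds = scan_length_bounds,
                 dlp_jitter_sd = dlp_jitter_sd),
            class = "sim_config")
}

# Unit-mean log-normal multiplier.
lognormal_noise <- function(sdlog) {
  if (sdlog == 0) return(1)
  exp(rnorm(1, mean = -sdlog^2 / 2, sd = sdlog))
}

# Truncated-normal draw conditional on the latent size factor z.
draw_sized <- function(par, bounds, z, loading) {
  cond_mean <- par[1] + par[2] * loading * z
  cond_sd <- par[2] * sqrt(1 - loading^2)
  rnorm_trunc(1, cond_mean, cond_sd, bounds[1], bounds[2])
}

#' Generate a synthetic LDCT examination cohort
#'
#' Samples `config$n` examinations: sex, then sex-conditional anthropometrics
#' (weight and chest dimensions sharing a latent size factor), effective
#' diameter, diagnostic-scan CTDIvol through the tube-current-modulation
#' model, scan DLP as `CTDIvol * length` with small multiplicative jitter,
#' and topogram dose metrics from the fixed topogram protocol.
#'
#' Every patient draws from an independent RNG substream derived
#' deterministically from `config$seed` and the patient index, so the same
#' `(seed, config)` always yields the same cohort and increasing `n` appends
#' patients without changing earlier rows. The caller's RNG state is left
#' untouched.
#'
#' @param config A [sim_config()].
#' @return An examination tibble following [exam_table_schema()].
#' @examples
#' exams <- generate_cohort(sim_config(n = 10, seed = 1))
#' @export
generate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    abort_config("`config` must be a `sim_config` object.")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })

  prof <- config$profile
  tcm <- config$tcm
  topo <- config$topogram
  loading <- sqrt(prof$latent_correlation)
  rows <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    # Splittable substream: a distinct, reproducible seed per patient.
    set.seed((config$seed + i * 2654435761) %% 2147483629)
    sex <- if (runif(1) < prof$male_fraction) "M" else "F"
    par <- if (sex == "M") prof$male else prof$female
    z <- rnorm(1)
    age <- rnorm_trunc(1, par$age[1], par$age[2],
                       prof$bounds$age[1], prof$bounds$age[2])
    height <- rnorm_trunc(1, par$height[1], par$height[2],
                          prof$bounds$height[1], prof$bounds$height[2])
    weight <- draw_sized(par$weight, prof$bounds$weight, z, loading)
    lat_a <- draw_sized(par$lat_dim_a, prof$bounds$lat_dim_a, z, loading)
    ap_b <- draw_sized(par$ap_dim_b, prof$bounds$ap_dim_b, z, loading)
    deff <- sqrt(lat_a * ap_b)

    ctdi <- tcm$baseline_ctdi *
      exp(tcm$size_exponent * (deff - tcm$reference_deff)) *
      lognormal_noise(tcm$lognormal_noise_sd)
    ctdi <- min(max(ctdi, tcm$ctdi_floor), tcm$ctdi_cap)

    scan_len <- rnorm_trunc(1, config$scan_length_mean, config$scan_length_sd,
                            config$scan_length_bounds[1],
                            config$scan_length_bounds[2])
    scan_dlp <- ctdi * (scan_len / 10) * lognormal_noise(config$dlp_jitter_sd)

    topo_ctdi <- rnorm_trunc(1, topo$ctdi_mean, topo$ctdi_sd,
                             topo$ctdi_bounds[1], topo$ctdi_bounds[2])
    topo_len <- rnorm_trunc(1, topo$length_mean, topo$length_sd,
                            topo$length_bounds[1], topo$length_bounds[2])
    topo_dlp <- rnorm_trunc(1, topo$dlp_mean, topo$dlp_sd,
                            topo$dlp_bounds[1], topo$dlp_bounds[2])

    rows[[i]] <- tibble::tibble(
      patient_id = sprintf("P%04d", i), sex = sex, age_years = age,
      weight_kg = weight, height_cm = height, lat_dim_a_cm = lat_a,
      ap_dim_b_cm = ap_b, topo_ctdivol_mgy = topo_ctdi,
      topo_dlp_mgycm = topo_dlp, topo_length_mm = topo_len,
      scan_ctdivol_mgy = ctdi, scan_dlp_mgycm = scan_dlp,
      scan_length_mm = scan_len
    )
  }
  dplyr::bind_rows(rows)
}

#' Estimate the tube-current-modulation size exponent from a cohort
#'
#' Ordinary least squares of `log(CTDIvol)` on the effective diameter; the
#' slope estimates the exponential dose-size rate of the TCM model that
#' produced the cohort. Serves as the parameter-recovery instrument for
#' [generate_cohort()].
#'
#' @param exams An examination table following [exam_table_schema()].
#' @return A list with `estimate`, `std_error`, `conf_int` (95%), and `n`.
#' @export
fit_tcm_exponent <- function(exams) {
  check_exam_table(exams)
  if (nrow(exams) < 10) {
    abort_insufficient("TCM exponent estimation needs at least 10 exams.")
  }
  if (any(exams$scan_ctdivol_mgy <= 0)) {
    abort_invalid("All diagnostic-scan CTDIvol values must be positive.")
  }
  deff <- compute_effective_diameter(exams$lat_dim_a_cm, exams$ap_dim_b_cm)
  if (isTRUE(all.equal(var(deff), 0)) || var(deff) < 1e-12) {
    abort_ctdose("Effective diameter is constant; the design is singular.",
                 class = "ctdose_singular_design")
  }
  fit <- lm(log(exams$scan_ctdivol_mgy) ~ deff)
  est <- summary(fit)$coefficients["deff", ]
  ci <- est[["Estimate"]] +
    c(-1, 1) * qt(0.975, fit$df.residual) * est[["Std. Error"]]
  list(estimate = est[["Estimate"]], std_error = est[["Std. Error"]],
       conf_int = ci, n = nrow(exams))
}
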