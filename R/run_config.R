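#' Run configuration for the analysis pipeline
#'
#' Bundles every tunable of an analysis run so results are reproducible from
#' `(input, config, seed)` alone. Round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param k_phantom Phantom for the conversion-factor model.
#' @param k_coeff_a,k_coeff_b,k_deff_range Conversion-factor fit parameters;
#'   `NULL` uses the phantom's published coefficients.
#' @param ed_conversion_f Effective-dose coefficient, mSv/(mGy·cm).
#' @param reference_diameter_cm Reference phantom diameter for the
#'   effective-diameter distribution, cm.
#' @param normality_alpha Significance level of the Shapiro-Wilk gate.
#' @param pooled_t Use the pooled-variance t-test instead of Welch.
#' @param clamp_deff Clamp out-of-range effective diameters instead of
#'   erroring.
#' @param round_digits Decimal places for rounded display columns.
#' @param seed Seed recorded with the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(k_phantom = "body_32cm", k_coeff_a = NULL,
                       k_coeff_b = NULL, k_deff_range = NULL,
                       ed_conversion_f = 0.014, reference_diameter_cm = 32,
                       normality_alpha = 0.05, pooled_t = FALSE,
                       clamp_deff = FALSE, round_digits = 2, seed = 17) {
  model <- k_factor_model(k_phantom, k_coeff_a, k_coeff_b, k_deff_range)
  check_positive(ed_conversion_f, "ed_conversion_f")
  check_positive(reference_diameter_cm, "reference_diameter_cm")
  if (!is.finite(normality_alpha) || normality_alpha <= 0 ||
      normality_alpha >= 1) {
    abort_config("`normality_alpha` must lie in (0, 1).")
  }
  structure(
    list(k_phantom = model$phantom, k_coeff_a = model$coeff_a,
         k_coeff_b = model$coeff_b, k_deff_range = model$deff_range,
         ed_conversion_f = ed_conversion_f,
         reference_diameter_cm = reference_diameter_cm,
         normality_alpha = normality_alpha,
         pooled_t = isTRUE(pooled_t), clamp_deff = isTRUE(clamp_deff),
         round_digits = as.integer(round_digits), seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) {
    abort_config("`config` must be a `run_config` object.")
  }
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("Configuration file not found: '%s'.", path))
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  known <- setdiff(known, c("k_deff_range"))
  args <- raw[intersect(names(raw), known)]
  args$k_deff_range <- if (!is.null(raw$k_deff_range))
    as.numeric(raw$k_deff_range) else NULL
  do.call(run_config, args)
}

# Stable content hash of a config for report provenance.
config_hash <- function(config) {
  rlang::hash(unclass(config))
}
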