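#' Size-dependent conversion-factor model (AAPM Report 204)
#'
#' The conversion factor \eqn{k} maps a phantom-referenced CTDIvol to a
#' patient-size-specific dose. AAPM Report 204 tabulates \eqn{k} against the
#' patient's effective diameter and also publishes an exponential fit to those
#' tables; this model uses the fit,
#' \deqn{k(D_{eff}) = a \, e^{-b \, D_{eff}},}
#' which is continuous and strictly decreasing in \eqn{D_{eff}}.
#'
#' @param phantom Reference phantom the scanner's CTDIvol refers to. Chest CT
#'   uses the 32-cm body phantom; the 16-cm head phantom coefficients are
#'   included for completeness.
#' @param coeff_a Fit amplitude (dimensionless), > 0.
#' @param coeff_b Fit decay rate (1/cm), > 0.
#' @param deff_range Effective-diameter validity range in cm; evaluation
#'   outside it is an error unless explicitly clamped.
#'
#' @return An object of class `k_factor_model`.
#' @seealso [k_factor()]
#' @examples
#' model <- k_factor_model()
#' k_factor(29.41, model)
#' @export
k_factor_model <- function(phantom = c("body_32cm", "head_16cm"),
                           coeff_a = NULL, coeff_b = NULL,
                           deff_range = NULL) {
  phantom <- match.arg(phantom)
  defaults <- switch(phantom,
    body_32cm = list(a = 3.704369, b = 0.03671937, range = c(8, 45)),
    head_16cm = list(a = 1.874799, b = 0.03871313, range = c(6, 40))
  )
  coeff_a <- coeff_a %||% defaults$a
  coeff_b <- coeff_b %||% defaults$b
  deff_range <- deff_range %||% defaults$range
  check_positive(coeff_a, "coeff_a")
  check_positive(coeff_b, "coeff_b")
  if (length(deff_range) != 2 || !all(is.finite(deff_range)) ||
      deff_range[1] <= 0 || diff(deff_range) <= 0) {
    abort_invalid("`deff_range` must be two increasing positive values (cm).")
  }
  structure(
    list(phantom = phantom, coeff_a = coeff_a, coeff_b = coeff_b,
         deff_range = deff_range),
    class = "k_factor_model"
  )
}

#' @export
print.k_factor_model <- function(x, ...) {
  cat(sprintf(
    "<k_factor_model> phantom: %s\n  k(Deff) = %.6f * exp(-%.8f * Deff), Deff in [%g, %g] cm\n",
    x$phantom, x$coeff_a, x$coeff_b, x$deff_range[1], x$deff_range[2]
  ))
  invisible(x)
}

#' Size-specific conversion factor k
#'
#' Evaluates the conversion factor \eqn{k} at one or more effective diameters.
#' `k` is strictly decreasing in `deff`: smaller patients absorb more dose per
#' unit phantom-referenced CTDIvol, so size correction raises the dose
#' estimate for small patients and lowers it for large ones.
#'
#' @param deff Effective diameter(s), cm.
#' @param model A [k_factor_model()].
#' @param clamp If `TRUE`, diameters outside the model's validity range are
#'   clamped to the nearest boundary (with a warning) instead of raising a
#'   range error. There is no silent extrapolation.
#'
#' @return Dimensionless conversion factor(s), same length as `deff`.
#' @examples
#' k_factor(c(24.07, 29.41), k_factor_model())
#' @export
k_factor <- function(deff, model = k_factor_model(), clamp = FALSE) {
  if (!inherits(model, "k_factor_model")) {
    abort_invalid("`model` must be a `k_factor_model` object.")
  }
  check_positive(deff, "deff")
  lo <- model$deff_range[1]
  hi <- model$deff_range[2]
  out_of_range <- deff < lo | deff > hi
  if (any(out_of_range)) {
    if (clamp) {
      rlang::warn(sprintf(
        "%d effective diameter(s) outside [%g, %g] cm clamped to the boundary.",
        sum(out_of_range), lo, hi
      ))
      deff <- pmin(pmax(deff, lo), hi)
    } else {
      abort_range(sprintf(
        "Effective diameter(s) %s outside the model validity range [%g, %g] cm; use `clamp = TRUE` to clamp.",
        paste(format(deff[out_of_range], digits = 4), collapse = ", "), lo, hi
      ))
    }
  }
  model$coeff_a * exp(-model$coeff_b * deff)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
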