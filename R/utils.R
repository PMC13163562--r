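# Condition helpers: every user-facing error carries a subclass so callers
# (and the CLI) can map failures to exit codes without string matching.

abort_ctdose <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "ctdose_error"), ...)
}

abort_invalid <- function(message, ...) {
  abort_ctdose(message, class = "ctdose_invalid_input", ...)
}

abort_range <- function(message, ...) {
  abort_ctdose(message, class = "ctdose_range_error", ...)
}

abort_schema <- function(message, ...) {
  abort_ctdose(message, class = "ctdose_schema_error", ...)
}

abort_empty <- function(message, ...) {
  abort_ctdose(message, class = "ctdose_empty_input", ...)
}

abort_insufficient <- function(message, ...) {
  abort_ctdose(message, class = "ctdose_insufficient_data", ...)
}

abort_config <- function(message, ...) {
  abort_ctdose(message, class = "ctdose_config_error", ...)
}

abort_io <- function(message, ...) {
  abort_ctdose(message, class = "ctdose_io_error", ...)
}

check_positive <- function(x, name) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x <= 0)) {
    abort_invalid(sprintf("`%s` must be a positive, finite number.", name),
                  field = name)
  }
  invisible(x)
}

check_non_negative <- function(x, name) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x < 0)) {
    abort_invalid(sprintf("`%s` must be a non-negative, finite number.", name),
                  field = name)
  }
  invisible(x)
}

# Truncated-normal sampling by inverse-CDF; exact, no rejection loop.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}
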