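# Classed conditions so callers can distinguish bad parameters, bad effector
# levels, bad input files and fitting failures programmatically.

abort_oxhlia <- function(message, class, ...) {
  stop(errorCondition(message,
                      ...,
                      class = c(class, "oxhlia_error")))
}

abort_param <- function(message, ...) {
  abort_oxhlia(message, "oxhlia_parameter_error", ...)
}

abort_effector <- function(message, ...) {
  abort_oxhlia(message, "oxhlia_effector_error", ...)
}

abort_data <- function(message, ...) {
  abort_oxhlia(message, "oxhlia_data_error", ...)
}

abort_fit <- function(message, ...) {
  abort_oxhlia(message, "oxhlia_fit_error", ...)
}

abort_convergence <- function(message, ...) {
  abort_oxhlia(message, c("oxhlia_convergence_error", "oxhlia_fit_error"), ...)
}

warn_domain <- function(message, ...) {
  warning(warningCondition(message, ...,
                           class = c("oxhlia_domain_warning", "oxhlia_warning")))
}

check_number <- function(x, name, positive = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_param(sprintf("`%s` must be a single non-missing number", name))
  }
  if (finite && !is.finite(x)) {
    abort_param(sprintf("`%s` must be finite", name))
  }
  if (positive && x <= 0) {
    abort_param(sprintf("`%s` must be strictly positive (got %g)", name, x))
  }
  invisible(x)
}
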