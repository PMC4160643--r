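#' Kinetic parameters of the Weibull erythrocyte-survival model
#'
#' Constructs the parameter triple of the survival kinetic model
#' \deqn{P(t) = K \exp[-\ln 2\, (t/\tau)^\alpha]}
#' where `K` is the asymptote (percent of the erythrocyte population on the
#' 0--100 scale), `tau` is the hemolytic half-life in minutes (the time at
#' which the surviving population equals `K/2`), and `alpha` is a
#' dimensionless shape parameter: `alpha < 1` gives power-law-like decay,
#' `alpha == 1` first-order decay, `alpha > 1` sigmoidal profiles.
#'
#' @param K asymptote, percent of the population (0--100 scale), `K > 0`.
#' @param tau half-life, minutes, `tau > 0`.
#' @param alpha dimensionless shape parameter, `alpha > 0`.
#' @return An object of class `kinetic_params`.
#' @seealso [weibull_survival()], [derived_kinetics()],
#'   [kinetic_params_from_shape_scale()]
#' @examples
#' p <- kinetic_params(K = 100, tau = 68.12, alpha = 4.59)
#' weibull_survival(c(0, 68.12, 90), p)
#' @export
kinetic_params <- function(K, tau, alpha) {
  check_number(K, "K")
  check_number(tau, "tau")
  check_number(alpha, "alpha")
  structure(list(K = K, tau = tau, alpha = alpha), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic parameters: K = %g %%, tau = %g min, alpha = %g\n",
              x$K, x$tau, x$alpha))
  invisible(x)
}

as_kinetic_params <- function(p) {
  if (inherits(p, "kinetic_params")) return(p)
  if (is.list(p) && all(c("K", "tau", "alpha") %in% names(p))) {
    return(kinetic_params(p$K, p$tau, p$alpha))
  }
  if (is.numeric(p) && length(p) == 3L && !is.null(names(p)) &&
      all(c("K", "tau", "alpha") %in% names(p))) {
    return(kinetic_params(p[["K"]], p[["tau"]], p[["alpha"]]))
  }
  abort_param("cannot interpret `params`: supply kinetic_params() or a named list with K, tau, alpha")
}

#' Convert the classical Weibull shape/scale parameters
#'
#' The classical two-parameter Weibull survival function
#' \eqn{P/100 = \exp[-(t/b)^a]} maps onto the half-life parameterization via
#' `alpha = a` and `tau = b * (ln 2)^(1/a)`.
#'
#' @param a classical shape parameter (`a > 0`).
#' @param b classical scale (position) parameter, minutes (`b > 0`).
#' @param K asymptote, percent (default 100).
#' @return A [kinetic_params()] object.
#' @export
kinetic_params_from_shape_scale <- function(a, b, K = 100) {
  check_number(a, "a")
  check_number(b, "b")
  kinetic_params(K = K, tau = b * log(2)^(1 / a), alpha = a)
}

## scalar core, vectorized in t; t = 0 returns K by continuity for any alpha
survival_eval <- function(t, K, tau, alpha) {
  K * exp(-log(2) * (t / tau)^alpha)
}

#' Surviving erythrocyte population at time t
#'
#' Evaluates the Weibull survival kinetic model. At `t = 0` the value is `K`
#' (by continuity when `alpha < 1`); at `t = tau` it is exactly `K/2`
#' (half-life identity).
#'
#' @param t time, minutes; non-negative, vectorized.
#' @param params a [kinetic_params()] object (or coercible named list).
#' @return Percent survival, same length as `t`, in `(0, K]`.
#' @examples
#' p <- kinetic_params(100, 68.12, 4.59)
#' weibull_survival(68.12, p)  # K/2
#' @export
weibull_survival <- function(t, params) {
  p <- as_kinetic_params(params)
  if (!is.numeric(t) || any(is.na(t)) || any(t < 0)) {
    abort_param("`t` must be a numeric vector of non-negative times (minutes)")
  }
  survival_eval(t, p$K, p$tau, p$alpha)
}

#' Instantaneous hemolysis rate -dP/dt
#'
#' Analytic rate of loss of the surviving population, in percent of the
#' population per minute. For `alpha < 1` the rate diverges at `t = 0`,
#' so `t = 0` is refused in that regime.
#'
#' @inheritParams weibull_survival
#' @return Rate `-dP/dt` (positive for `t > 0`), percent/min.
#' @export
hemolysis_rate <- function(t, params) {
  p <- as_kinetic_params(params)
  if (!is.numeric(t) || any(is.na(t)) || any(t < 0)) {
    abort_param("`t` must be a numeric vector of non-negative times (minutes)")
  }
  if (p$alpha < 1 && any(t == 0)) {
    abort_param("the hemolysis rate is singular at t = 0 when alpha < 1")
  }
  ln2 <- log(2)
  ln2 * p$alpha / p$tau * (t / p$tau)^(p$alpha - 1) *
    survival_eval(t, p$K, p$tau, p$alpha)
}

# G = (alpha - 1)/alpha; positive iff alpha > 1 (sigmoidal regime)
g_of_alpha <- function(alpha) (alpha - 1) / alpha

# lambda = tau * lag_coefficient(alpha); requires alpha > 1
lag_coefficient <- function(alpha) {
  G <- g_of_alpha(alpha)
  log(2)^(1 / alpha) *
    (G^(1 / alpha) + (exp(-G) - 1) / (alpha * G^G * exp(-G)))
}

#' Closed-form derived kinetic parameters
#'
#' Computes, from a `(K, tau, alpha)` triple, the quantities that summarize a
#' hemolysis curve for assay reporting, with `G = (alpha - 1)/alpha`:
#' \itemize{
#'   \item `v_tau = K * alpha * ln2 / (2 * tau)` — hemolysis rate at the
#'     half-life point, percent/min;
#'   \item `v_m = (K * alpha / tau) * (ln2)^(1/alpha) * G^G * exp(-G)` —
#'     maximum hemolysis rate, percent/min;
#'   \item `lag = tau * (ln2)^(1/alpha) * [G^(1/alpha) + (exp(-G) - 1) /
#'     (alpha * G^G * exp(-G))]` — lag phase, minutes;
#'   \item `t_star = tau * (G / ln2)^(1/alpha)` — time of maximum rate, minutes.
#' }
#' `v_m`, `lag` and `t_star` exist only in the sigmoidal regime
#' (`alpha > 1`); otherwise they are returned as `NA` with `defined = FALSE`
#' markers so that downstream reports stay total rather than erroring.
#'
#' @param params a [kinetic_params()] object.
#' @return Object of class `derived_kinetics`: a list with `v_tau`, `v_m`,
#'   `lag`, `t_star`, `G` and a logical vector `defined`.
#' @examples
#' derived_kinetics(kinetic_params(100, 68.12, 4.59))
#' @export
derived_kinetics <- function(params) {
  p <- as_kinetic_params(params)
  ln2 <- log(2)
  v_tau <- p$K * p$alpha * ln2 / (2 * p$tau)
  if (p$alpha > 1) {
    G <- g_of_alpha(p$alpha)
    v_m <- (p$K * p$alpha / p$tau) * ln2^(1 / p$alpha) * G^G * exp(-G)
    lag <- p$tau * lag_coefficient(p$alpha)
    t_star <- p$tau * (G / ln2)^(1 / p$alpha)
    defined <- c(v_tau = TRUE, v_m = TRUE, lag = TRUE, t_star = TRUE)
  } else {
    G <- g_of_alpha(p$alpha)
    v_m <- NA_real_
    lag <- NA_real_
    t_star <- NA_real_
    defined <- c(v_tau = TRUE, v_m = FALSE, lag = FALSE, t_star = FALSE)
  }
  structure(list(v_tau = v_tau, v_m = v_m, lag = lag, t_star = t_star,
                 G = G, defined = defined, params = p),
            class = "derived_kinetics")
}

#' @export
print.derived_kinetics <- function(x, digits = 4, ...) {
  fmt <- function(v, unit) {
    if (is.na(v)) "undefined (requires alpha > 1)" else
      paste(signif(v, digits), unit)
  }
  cat("Derived kinetic parameters:\n")
  cat("  v_tau (rate at half-life):", fmt(x$v_tau, "%/min"), "\n")
  cat("  v_m   (maximum rate):     ", fmt(x$v_m, "%/min"), "\n")
  cat("  lag   (lag phase):        ", fmt(x$lag, "min"), "\n")
  cat("  t*    (time of max rate): ", fmt(x$t_star, "min"), "\n")
  invisible(x)
}

#' @export
as.data.frame.derived_kinetics <- function(x, ...) {
  data.frame(v_tau = x$v_tau, v_m = x$v_m, lag = x$lag,
             t_star = x$t_star, G = x$G)
}

## ---- reparameterized forms -------------------------------------------------
## Each explicit-parameter form is evaluated by exact inversion: the half-life
## implied by the supplied derived parameter is recovered in closed form and
## the base model evaluated with it. This keeps the three forms pointwise
## identical to the (K, tau, alpha) form by construction.

#' Recover the half-life from a derived kinetic parameter
#'
#' Closed-form inversions of the derived-parameter formulas of
#' [derived_kinetics()]. `tau_from_vm()` and `tau_from_lag()` require
#' `alpha > 1`.
#'
#' @param K asymptote, percent.
#' @param v_m,v_tau,lag the derived parameter value (percent/min for the
#'   rates, minutes for the lag).
#' @param alpha shape parameter.
#' @return Half-life `tau`, minutes.
#' @export
tau_from_vtau <- function(K, v_tau, alpha) {
  check_number(K, "K"); check_number(v_tau, "v_tau"); check_number(alpha, "alpha")
  K * alpha * log(2) / (2 * v_tau)
}

#' @rdname tau_from_vtau
#' @export
tau_from_vm <- function(K, v_m, alpha) {
  check_number(K, "K"); check_number(v_m, "v_m"); check_number(alpha, "alpha")
  if (alpha <= 1) abort_param("the v_m form requires alpha > 1")
  G <- g_of_alpha(alpha)
  K * alpha * log(2)^(1 / alpha) * G^G * exp(-G) / v_m
}

#' @rdname tau_from_vtau
#' @export
tau_from_lag <- function(lag, alpha) {
  check_number(lag, "lag"); check_number(alpha, "alpha")
  if (alpha <= 1) abort_param("the lag-phase form requires alpha > 1")
  lag / lag_coefficient(alpha)
}

#' Reparameterized survival forms with explicit derived parameters
#'
#' Evaluate the survival model parameterized directly by the maximum rate
#' (`survival_from_vm`), the rate at the half-life (`survival_from_vtau`) or
#' the lag phase (`survival_from_lambda`) instead of the half-life itself.
#' These are the forms used when a confidence interval for a derived
#' parameter is wanted directly from a fit. Each is pointwise identical to
#' [weibull_survival()] evaluated with the corresponding half-life.
#'
#' @param t time, minutes (vectorized).
#' @param K asymptote, percent.
#' @param v_m,v_tau,lag the explicit parameter (see [derived_kinetics()]).
#' @param alpha shape parameter (`alpha > 1` for the `v_m` and lag forms).
#' @return Percent survival.
#' @examples
#' p <- kinetic_params(100, 68.12, 4.59)
#' d <- derived_kinetics(p)
#' survival_from_vtau(90, 100, d$v_tau, 4.59)  # == weibull_survival(90, p)
#' @export
survival_from_vm <- function(t, K, v_m, alpha) {
  weibull_survival(t, kinetic_params(K, tau_from_vm(K, v_m, alpha), alpha))
}

#' @rdname survival_from_vm
#' @export
survival_from_vtau <- function(t, K, v_tau, alpha) {
  weibull_survival(t, kinetic_params(K, tau_from_vtau(K, v_tau, alpha), alpha))
}

#' @rdname survival_from_vm
#' @export
survival_from_lambda <- function(t, K, lag, alpha) {
  weibull_survival(t, kinetic_params(K, tau_from_lag(lag, alpha), alpha))
}
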