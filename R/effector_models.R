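#' Phenomenological effector-modifier functions
#'
#' An effector (antioxidant, prooxidant, surfactant, salt, temperature, ...)
#' perturbs a kinetic parameter \eqn{\theta} of the survival model through a
#' dimensionless modifier function \eqn{f(e)} of the effector level `e`,
#' composed multiplicatively as \eqn{m_\theta(e) = \theta_C [1 + f(e)]} with
#' \eqn{\theta_C} the unperturbed (control) value. Four shapes are provided:
#'
#' \itemize{
#'   \item linear: `L(e) = l1 * e + l2` (slope `l1` per effector unit,
#'     intercept `l2`; `l2 = 0` keeps the control curve as the `e = 0` slice);
#'   \item hyperbolic: `H(e) = h1 * (1 - exp(h2 * e))` (asymptote `h1`,
#'     rate `h2` per effector unit; saturating when `h2 < 0`);
#'   \item sigmoidal: `S(e) = s1 * exp(-ln2 * (e/s2)^s3)` (asymptote `s1`
#'     at `e = 0`, half-effect level `s2`, shape `s3`); decreasing in `e`,
#'     with `S(s2) = s1/2` exactly;
#'   \item bell: `B(e) = b1 * exp((b3/b2) * (1 - (e/b4)^b2 + b2*log(e/b4)))`
#'     (maximum `b1` attained at `e = b4`; `b2` width-related, `b3`
#'     asymmetry-related). The bell shape is an asymmetric log-bell; see the
#'     methods vignette for the rationale behind this exact algebraic form.
#' }
#'
#' @param l1,l2 linear slope (parameter units per effector unit as a
#'   fraction of the control) and dimensionless intercept.
#' @param h1,h2 hyperbolic asymptote and rate (1/effector units).
#' @param s1,s2,s3 sigmoidal asymptote, half-effect level (`s2 > 0`) and
#'   shape (`s3 > 0`).
#' @param b1,b2,b3,b4 bell maximum, width (`b2 > 0`), asymmetry and level of
#'   the maximum (`b4 > 0`).
#' @return An object of class `modifier_spec`.
#' @seealso [evaluate_modifier()], [modified_parameter()], [effector_model()]
#' @export
linear_modifier <- function(l1, l2 = 0) {
  check_number(l1, "l1", positive = FALSE)
  check_number(l2, "l2", positive = FALSE)
  new_modifier("linear", c(l1 = l1, l2 = l2))
}

#' @rdname linear_modifier
#' @export
hyperbolic_modifier <- function(h1, h2) {
  check_number(h1, "h1", positive = FALSE)
  check_number(h2, "h2", positive = FALSE)
  new_modifier("hyperbolic", c(h1 = h1, h2 = h2))
}

#' @rdname linear_modifier
#' @export
sigmoidal_modifier <- function(s1, s2, s3) {
  check_number(s1, "s1", positive = FALSE)
  check_number(s2, "s2")
  check_number(s3, "s3")
  new_modifier("sigmoidal", c(s1 = s1, s2 = s2, s3 = s3))
}

#' @rdname linear_modifier
#' @export
bell_modifier <- function(b1, b2, b3, b4) {
  check_number(b1, "b1", positive = FALSE)
  check_number(b2, "b2")
  check_number(b3, "b3", positive = FALSE)
  check_number(b4, "b4")
  new_modifier("bell", c(b1 = b1, b2 = b2, b3 = b3, b4 = b4))
}

new_modifier <- function(kind, coefficients) {
  structure(list(kind = kind, coefficients = coefficients),
            class = "modifier_spec")
}

#' @export
print.modifier_spec <- function(x, ...) {
  cat(sprintf("%s modifier: %s\n", x$kind,
              paste(names(x$coefficients), signif(x$coefficients, 5),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

modifier_coef_names <- function(kind) {
  switch(kind,
         linear = c("l1", "l2"),
         hyperbolic = c("h1", "h2"),
         sigmoidal = c("s1", "s2", "s3"),
         bell = c("b1", "b2", "b3", "b4"),
         abort_param(sprintf("unknown modifier kind '%s'", kind)))
}

#' Evaluate a modifier function f(e)
#'
#' @param spec a `modifier_spec` from [linear_modifier()] and friends.
#' @param e effector level(s); must be `> 0` for the sigmoidal and bell
#'   shapes (their log/power terms), `>= 0` otherwise.
#' @return The dimensionless perturbation `f(e)`, vectorized over `e`.
#' @export
evaluate_modifier <- function(spec, e) {
  if (!inherits(spec, "modifier_spec")) {
    abort_param("`spec` must be a modifier_spec")
  }
  if (!is.numeric(e) || any(is.na(e))) {
    abort_effector("`e` must be numeric and non-missing")
  }
  k <- spec$coefficients
  switch(spec$kind,
    linear = {
      if (any(e < 0)) abort_effector("linear modifier requires e >= 0")
      k[["l1"]] * e + k[["l2"]]
    },
    hyperbolic = {
      if (any(e < 0)) abort_effector("hyperbolic modifier requires e >= 0")
      k[["h1"]] * (1 - exp(k[["h2"]] * e))
    },
    sigmoidal = {
      if (any(e <= 0)) abort_effector("sigmoidal modifier requires e > 0")
      k[["s1"]] * exp(-log(2) * (e / k[["s2"]])^k[["s3"]])
    },
    bell = {
      if (any(e <= 0)) abort_effector("bell modifier requires e > 0")
      r <- (e / k[["b4"]])^k[["b2"]]
      k[["b1"]] * exp((k[["b3"]] / k[["b2"]]) * (1 - r + log(r)))
    })
}

#' Compose a control parameter with a modifier
#'
#' Applies the multiplicative composition `m_theta = theta_C * (1 + f(e))`.
#' A non-positive composed value leaves the kinetic-parameter domain; it is
#' returned as computed but flagged with a classed warning
#' (`oxhlia_domain_warning`), because during fitting intermediate iterates
#' may stray before converging to a valid optimum.
#'
#' @param theta_c control (unperturbed) parameter value, `> 0`.
#' @param spec a `modifier_spec`.
#' @param e effector level(s).
#' @return The modified parameter value(s) `m_theta(e)`.
#' @export
modified_parameter <- function(theta_c, spec, e) {
  check_number(theta_c, "theta_c")
  m <- theta_c * (1 + evaluate_modifier(spec, e))
  if (any(m <= 0)) {
    warn_domain(sprintf(
      "modified parameter is non-positive at %d effector level(s)",
      sum(m <= 0)))
  }
  m
}

#' Time-effector survival model
#'
#' Bundles a control kinetic curve with modifier functions attached to
#' chosen parameters, defining the bivariate survival surface
#' \deqn{P(t, e) = m_K \exp[-\ln 2\, (t/m_\tau)^{m_\alpha}]}
#' where each \eqn{m_\theta(e) = \theta_C [1 + f_\theta(e)]} and unmodified
#' parameters pass through as their control values.
#'
#' Modifiers may target the native parameters (`"K"`, `"tau"`, `"alpha"`) or
#' exactly one of the derived parameters (`"v_m"`, `"v_tau"`, `"lag"`); in
#' the latter case the control derived value is perturbed and the implied
#' half-life recovered in closed form (useful e.g. for temperature effects
#' expressed on the half-life rate).
#'
#' @param control a [kinetic_params()] object (the `e = 0` / unperturbed
#'   curve when every modifier has `f(0) = 0`).
#' @param modifiers named list of `modifier_spec` objects; names among
#'   `K`, `tau`, `alpha`, `v_m`, `v_tau`, `lag`. At most one of
#'   `tau`/`v_m`/`v_tau`/`lag` may be modified.
#' @return An object of class `effector_model`.
#' @examples
#' m <- effector_model(kinetic_params(100, 70.5, 4.83),
#'                     list(tau = linear_modifier(0.0086),
#'                          alpha = linear_modifier(0.0121)))
#' bivariate_survival(90, 50, m)
#' @export
effector_model <- function(control, modifiers = list()) {
  control <- as_kinetic_params(control)
  if (length(modifiers)) {
    if (is.null(names(modifiers)) || any(names(modifiers) == "")) {
      abort_param("`modifiers` must be a fully named list")
    }
    ok <- c("K", "tau", "alpha", "v_m", "v_tau", "lag")
    bad <- setdiff(names(modifiers), ok)
    if (length(bad)) {
      abort_param(sprintf("unknown modifier target(s): %s",
                          paste(bad, collapse = ", ")))
    }
    half_life_targets <- intersect(names(modifiers),
                                   c("tau", "v_m", "v_tau", "lag"))
    if (length(half_life_targets) > 1) {
      abort_param("only one of tau, v_m, v_tau, lag may carry a modifier")
    }
    for (m in modifiers) {
      if (!inherits(m, "modifier_spec")) {
        abort_param("every element of `modifiers` must be a modifier_spec")
      }
    }
  }
  structure(list(control = control, modifiers = modifiers),
            class = "effector_model")
}

#' @export
print.effector_model <- function(x, ...) {
  cat("Effector model\n")
  cat(sprintf("  control: K = %g, tau = %g, alpha = %g\n",
              x$control$K, x$control$tau, x$control$alpha))
  if (!length(x$modifiers)) {
    cat("  no modifiers (control curve only)\n")
  } else {
    for (nm in names(x$modifiers)) {
      m <- x$modifiers[[nm]]
      cat(sprintf("  %s <- %s(%s)\n", nm, m$kind,
                  paste(names(m$coefficients), signif(m$coefficients, 5),
                        sep = "=", collapse = ", ")))
    }
  }
  invisible(x)
}

#' Kinetic parameters at a given effector level
#'
#' Composes every modifier of an [effector_model()] at level `e` and returns
#' the resulting `(m_K, m_tau, m_alpha)` triple. K and alpha modifiers are
#' applied first so that a derived-parameter modifier (on `v_m`, `v_tau` or
#' `lag`) is inverted with the already-modified K and alpha.
#'
#' @param model an `effector_model`.
#' @param e a single effector level.
#' @return A [kinetic_params()] object.
#' @export
params_at_level <- function(model, e) {
  if (!inherits(model, "effector_model")) {
    abort_param("`model` must be an effector_model")
  }
  ctl <- model$control
  mods <- model$modifiers
  K <- if (!is.null(mods$K)) ctl$K * (1 + evaluate_modifier(mods$K, e)) else ctl$K
  alpha <- if (!is.null(mods$alpha)) {
    ctl$alpha * (1 + evaluate_modifier(mods$alpha, e))
  } else ctl$alpha
  tau <- ctl$tau
  if (!is.null(mods$tau)) {
    tau <- ctl$tau * (1 + evaluate_modifier(mods$tau, e))
  } else if (!is.null(mods$v_tau)) {
    v0 <- ctl$K * ctl$alpha * log(2) / (2 * ctl$tau)
    tau <- tau_from_vtau(K, v0 * (1 + evaluate_modifier(mods$v_tau, e)), alpha)
  } else if (!is.null(mods$v_m)) {
    v0 <- derived_kinetics(ctl)$v_m
    tau <- tau_from_vm(K, v0 * (1 + evaluate_modifier(mods$v_m, e)), alpha)
  } else if (!is.null(mods$lag)) {
    l0 <- derived_kinetics(ctl)$lag
    tau <- tau_from_lag(l0 * (1 + evaluate_modifier(mods$lag, e)), alpha)
  }
  if (K <= 0 || tau <= 0 || alpha <= 0) {
    abort_param(sprintf(
      "modified parameters leave the valid domain at e = %g (K = %g, tau = %g, alpha = %g)",
      e, K, tau, alpha))
  }
  kinetic_params(K, tau, alpha)
}

#' Bivariate time-effector survival surface
#'
#' Evaluates the surviving population at time `t` under effector level `e`:
#' the univariate survival model with every parameter composed through its
#' modifier at that level.
#'
#' @param t time(s), minutes.
#' @param e effector level(s); recycled against `t` as usual.
#' @param model an [effector_model()].
#' @return Percent survival, vectorized over `(t, e)`.
#' @export
bivariate_survival <- function(t, e, model) {
  if (!inherits(model, "effector_model")) {
    abort_param("`model` must be an effector_model")
  }
  n <- max(length(t), length(e))
  t <- rep_len(t, n)
  e <- rep_len(e, n)
  out <- numeric(n)
  for (lev in unique(e)) {
    idx <- e == lev
    out[idx] <- weibull_survival(t[idx], params_at_level(model, lev))
  }
  out
}

#' Preset time-effector model templates
#'
#' Named modifier configurations for the effector classes commonly studied
#' in hemolysis assays. Each preset states which kinetic parameter is
#' perturbed by which modifier shape; the coefficients are free parameters
#' to be estimated by [fit_bivariate()].
#'
#' \describe{
#'   \item{`"antioxidant-L"`}{Linear increase of `tau` and of `alpha` with
#'     dose, intercepts fixed at 0 (the control curve anchors the surface);
#'     the asymptote `K` carries no modifier because in an open system with
#'     excess radical initiator hemolysis is eventually complete at every
#'     dose. The `tau` slope `l1` is the headline potency coefficient.}
#'   \item{`"prooxidant-H"`}{Saturating (hyperbolic) decrease of `tau`,
#'     linear increase of `alpha` (e.g. radical-initiator dose).}
#'   \item{`"surfactant"`}{Linear modifier on `tau`, hyperbolic on `alpha`.}
#'   \item{`"temperature-B"`}{Bell modifier on the half-life rate `v_tau`
#'     (rates peak at an optimum temperature), linear on `alpha`.}
#' }
#'
#' @param name preset name.
#' @param free_l2 logical: free the linear intercepts instead of fixing them
#'   at 0.
#' @return A template list used by [fit_bivariate()]: per-target modifier
#'   kind plus fixed-coefficient assignments.
#' @export
effector_preset <- function(name = c("antioxidant-L", "prooxidant-H",
                                     "surfactant", "temperature-B"),
                            free_l2 = FALSE) {
  name <- match.arg(name)
  lin <- function() {
    if (free_l2) list(kind = "linear", fixed = c())
    else list(kind = "linear", fixed = c(l2 = 0))
  }
  mods <- switch(name,
    "antioxidant-L" = list(tau = lin(), alpha = lin()),
    "prooxidant-H" = list(tau = list(kind = "hyperbolic", fixed = c()),
                          alpha = lin()),
    "surfactant" = list(tau = lin(),
                        alpha = list(kind = "hyperbolic", fixed = c())),
    "temperature-B" = list(v_tau = list(kind = "bell", fixed = c()),
                           alpha = lin()))
  structure(list(name = name, modifiers = mods), class = "effector_template")
}
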