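## Nonlinear least-squares estimation for survival kinetics: per-curve
## univariate fits, simultaneous bivariate time-effector fits, and the
## linearized inference suite (Student-t CIs, Fisher F, adjusted R^2).
## The optimizer is Levenberg-Marquardt (minpack.lm); everything around it
## (parameterizations, initialization, inference) lives here.

default_nls_control <- function(control = list()) {
  base <- list(ftol = 1e-10, ptol = 1e-10, gtol = 0, maxiter = 1000,
               maxfev = 100000L)
  base[names(control)] <- control
  base
}

numeric_jacobian <- function(fn, par, rel_step = 1e-6) {
  f0 <- fn(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- rel_step * max(abs(par[j]), 1)
    up <- par; up[j] <- par[j] + h
    dn <- par; dn[j] <- par[j] - h
    J[, j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  colnames(J) <- names(par)
  J
}

## Shared LM driver. predict_fn(par) must return a prediction for every
## observation (finite, or the iterate is rejected with a flat penalty).
run_nls <- function(observed, predict_fn, start, lower, upper,
                    weights = NULL, control = list()) {
  ctl <- default_nls_control(control)
  sw <- if (is.null(weights)) rep(1, length(observed)) else sqrt(weights)
  resid_fn <- function(par) {
    pred <- tryCatch(predict_fn(par), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) {
      return(rep(1e6, length(observed)))
    }
    (observed - pred) * sw
  }
  out <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = ctl$ftol, ptol = ctl$ptol, gtol = ctl$gtol,
      maxiter = ctl$maxiter, maxfev = ctl$maxfev))
  par <- stats::setNames(out$par, names(start))
  fitted <- predict_fn(par)
  list(par = par,
       fitted = fitted,
       residuals = observed - fitted,
       sse = sum(((observed - fitted) * sw)^2),
       converged = out$info %in% c(1L, 2L, 3L, 4L, 6L, 7L),
       info = out$info,
       message = out$message,
       iterations = out$niter)
}

#' Linearized inference for a nonlinear least-squares optimum
#'
#' Given the Jacobian of the model predictions with respect to the
#' parameters at the optimum, computes the classical linearized (Gauss)
#' approximation: parameter covariance \eqn{(J'J)^{-1} SSE/(n-p)}, standard
#' errors, two-sided Student-t confidence half-widths, per-parameter t
#' tests, the Fisher F test of model consistency
#' (regression mean square over residual mean square), the determination
#' coefficient of observed vs predicted and its adjusted form
#' \eqn{R^2_{adj} = 1 - (1-R^2)(n-1)/(n-p-1)}.
#'
#' @param estimates named parameter estimates at the optimum.
#' @param jacobian `n x p` Jacobian of predictions w.r.t. parameters.
#' @param residuals observed minus predicted, length `n`.
#' @param observed the observed responses (needed for `R^2` and the F test).
#' @param level confidence level (default 0.95, i.e. alpha = 0.05).
#' @return A list with `estimates`, `std_errors`, `ci_halfwidths`,
#'   `t_values`, `p_values`, `significant` (t test at `1 - level`), `dof`,
#'   `sse`, `r2`, `r2_adj`, `f_statistic`, `f_pvalue`, `covariance`.
#' @export
nls_inference <- function(estimates, jacobian, residuals, observed,
                          level = 0.95) {
  n <- length(residuals)
  p <- ncol(jacobian)
  if (length(observed) != n || nrow(jacobian) != n) {
    abort_fit("jacobian, residuals and observed must agree in length")
  }
  dof <- n - p
  if (dof <= 0) {
    abort_fit(sprintf(
      "under-determined fit: %d observations for %d parameters", n, p))
  }
  sse <- sum(residuals^2)
  jtj <- crossprod(jacobian)
  rk <- qr(jtj)$rank
  if (rk < p) {
    ev <- eigen(jtj, symmetric = TRUE)
    null_vecs <- ev$vectors[, (rk + 1):p, drop = FALSE]
    culprits <- unique(colnames(jacobian)[apply(abs(null_vecs), 2, which.max)])
    abort_fit(sprintf(
      "rank-deficient fit: parameter direction(s) not identifiable (%s)",
      paste(culprits, collapse = ", ")))
  }
  covariance <- solve(jtj) * sse / dof
  dimnames(covariance) <- list(names(estimates), names(estimates))
  se <- sqrt(pmax(diag(covariance), 0))
  tq <- stats::qt(1 - (1 - level) / 2, dof)
  ci <- tq * se
  tv <- ifelse(se > 0, estimates / se, ifelse(estimates == 0, 0, Inf))
  pv <- 2 * stats::pt(abs(tv), dof, lower.tail = FALSE)
  sstot <- sum((observed - mean(observed))^2)
  r2 <- if (sstot > 0) 1 - sse / sstot else NA_real_
  r2_adj <- if (!is.na(r2) && n - p - 1 > 0) {
    1 - (1 - r2) * (n - 1) / (n - p - 1)
  } else r2
  df1 <- max(p - 1, 1)
  fstat <- if (sse > 0) ((sstot - sse) / df1) / (sse / dof) else Inf
  fp <- if (is.finite(fstat)) {
    stats::pf(fstat, df1, dof, lower.tail = FALSE)
  } else 0
  list(estimates = estimates, std_errors = stats::setNames(se, names(estimates)),
       ci_halfwidths = stats::setNames(ci, names(estimates)),
       t_values = stats::setNames(tv, names(estimates)),
       p_values = stats::setNames(pv, names(estimates)),
       significant = stats::setNames(pv < (1 - level), names(estimates)),
       dof = dof, sse = sse, r2 = r2, r2_adj = r2_adj,
       f_statistic = fstat, f_pvalue = fp, covariance = covariance)
}

new_oxhlia_fit <- function(run, inference, kind, base, data, extra = list()) {
  out <- c(inference,
           list(residuals = run$residuals, fitted = run$fitted,
                n_obs = length(run$residuals),
                converged = run$converged, iterations = run$iterations,
                optimizer_message = run$message,
                kind = kind, base = base, data = data),
           extra)
  class(out) <- "oxhlia_fit"
  out
}

## parameter names and (K, tau, alpha) mapping for each base form
base_param_names <- function(base) {
  switch(base,
         eq5 = c("K", "tau", "alpha"),
         vm = c("K", "v_m", "alpha"),
         vtau = c("K", "v_tau", "alpha"),
         lambda = c("K", "lag", "alpha"))
}

base_to_kinetic <- function(par, base) {
  switch(base,
    eq5 = kinetic_params(par[["K"]], par[["tau"]], par[["alpha"]]),
    vm = kinetic_params(par[["K"]],
                        tau_from_vm(par[["K"]], par[["v_m"]], par[["alpha"]]),
                        par[["alpha"]]),
    vtau = kinetic_params(par[["K"]],
                          tau_from_vtau(par[["K"]], par[["v_tau"]], par[["alpha"]]),
                          par[["alpha"]]),
    lambda = kinetic_params(par[["K"]],
                            tau_from_lag(par[["lag"]], par[["alpha"]]),
                            par[["alpha"]]))
}

kinetic_to_base <- function(p, base) {
  d <- if (base %in% c("vm", "vtau", "lambda")) derived_kinetics(p) else NULL
  switch(base,
         eq5 = c(K = p$K, tau = p$tau, alpha = p$alpha),
         vm = c(K = p$K, v_m = d$v_m, alpha = p$alpha),
         vtau = c(K = p$K, v_tau = d$v_tau, alpha = p$alpha),
         lambda = c(K = p$K, lag = d$lag, alpha = p$alpha))
}

## data-driven starting triple: K from the plateau, tau from the first
## half-maximum crossing (linear interpolation), alpha mid-range sigmoidal
initial_kinetic_guess <- function(time, response) {
  ord <- order(time)
  t <- time[ord]; y <- response[ord]
  K0 <- max(y)
  half <- K0 / 2
  below <- which(y <= half)
  tau0 <- if (!length(below) || below[1] == 1L) {
    max(t[length(t)], 1)
  } else {
    i <- below[1]
    t[i - 1] + (t[i] - t[i - 1]) * (y[i - 1] - half) /
      max(y[i - 1] - y[i], .Machine$double.eps)
  }
  kinetic_params(max(K0, 1e-3), max(tau0, 1e-3), 4)
}

base_bounds <- function(base, tmax) {
  lo <- c(K = 1e-6, mid = 1e-8, alpha = if (base %in% c("vm", "lambda")) 1.01 else 0.05)
  hi <- c(K = 120, mid = if (base == "lambda") 10 * tmax else Inf, alpha = 50)
  if (base == "eq5") {
    lo[2] <- 1e-6
    hi[2] <- 10 * tmax
  }
  list(lower = unname(lo), upper = unname(hi))
}

#' Fit the survival kinetic model to one hemolysis curve
#'
#' Estimates the three parameters of the Weibull survival model from a
#' single time series of percent survival by unweighted nonlinear least
#' squares, in any of four algebraically equivalent parameterizations:
#' the native half-life form (`base = "eq5"`), or the forms with an
#' explicit maximum rate (`"vm"`), half-life rate (`"vtau"`) or lag phase
#' (`"lambda"`), which yield direct confidence intervals for those derived
#' parameters. Starting values are data-driven (plateau, first half-maximum
#' crossing, mid-range shape) and the optimum is identical across bases up
#' to the closed-form parameter mapping.
#'
#' @param time observation times, minutes.
#' @param response percent survival at each time (0--100 scale; values
#'   slightly outside from measurement noise are acceptable).
#' @param base parameterization to fit.
#' @param start optional named starting values (in the base's parameters);
#'   unnamed entries of the default are kept.
#' @param weights optional non-negative observation weights (default
#'   unweighted, matching the homoscedastic assay noise).
#' @param level confidence level for intervals (default 0.95).
#' @param control optimizer settings (`ftol`, `ptol`, `maxiter`).
#' @return An object of class `oxhlia_fit`; see [nls_inference()] for the
#'   inference fields. Also carries `kinetic_params` (the implied
#'   `(K, tau, alpha)`) and `derived` ([derived_kinetics()] at the optimum).
#' @examples
#' p <- kinetic_params(100, 68.12, 4.59)
#' t <- seq(0, 180, by = 15)
#' fit <- fit_univariate(t, weibull_survival(t, p))
#' coef(fit)
#' @export
fit_univariate <- function(time, response,
                           base = c("eq5", "vm", "vtau", "lambda"),
                           start = NULL, weights = NULL, level = 0.95,
                           control = list()) {
  base <- match.arg(base)
  if (!is.numeric(time) || !is.numeric(response) ||
      length(time) != length(response)) {
    abort_data("`time` and `response` must be numeric vectors of equal length")
  }
  if (any(is.na(time)) || any(is.na(response)) || any(time < 0)) {
    abort_data("times must be non-negative and responses non-missing")
  }
  if (length(time) < 4) {
    abort_fit("under-determined fit: at least 4 observations are needed for 3 parameters")
  }
  if (stats::var(response) == 0) {
    abort_fit("degenerate series: constant response carries no kinetic information")
  }
  guess <- initial_kinetic_guess(time, response)
  start0 <- kinetic_to_base(guess, base)
  if (!is.null(start)) {
    start0[names(start)] <- start
  }
  bb <- base_bounds(base, max(time, 1))
  start0 <- pmin(pmax(start0, bb$lower), bb$upper)
  predict_fn <- function(par) {
    names(par) <- base_param_names(base)
    weibull_survival(time, base_to_kinetic(par, base))
  }
  run <- run_nls(response, predict_fn, stats::setNames(start0, base_param_names(base)),
                 bb$lower, bb$upper, weights, control)
  J <- numeric_jacobian(predict_fn, run$par)
  inf <- nls_inference(run$par, J, run$residuals, response, level)
  kp <- base_to_kinetic(run$par, base)
  fit <- new_oxhlia_fit(run, inf, kind = "univariate", base = base,
                        data = data.frame(time = time, response = response),
                        extra = list(kinetic_params = kp,
                                     derived = derived_kinetics(kp)))
  if (!run$converged) {
    abort_convergence(sprintf(
      "univariate fit did not converge (optimizer: %s)", run$message),
      fit = fit)
  }
  fit
}

## ---- bivariate (simultaneous) fitting --------------------------------------

coef_bounds <- function(kind) {
  nm <- modifier_coef_names(kind)
  lo <- stats::setNames(rep(-Inf, length(nm)), nm)
  hi <- stats::setNames(rep(Inf, length(nm)), nm)
  if (kind == "sigmoidal") lo[c("s2", "s3")] <- 1e-6
  if (kind == "bell") lo[c("b2", "b4")] <- 1e-6
  list(lower = lo, upper = hi)
}

## crude shape-specific initial coefficients from per-level relative
## perturbations f_hat(e) = theta_hat(e)/theta_C - 1
init_modifier_coefs <- function(kind, e, f_hat) {
  ok <- is.finite(f_hat)
  e <- e[ok]; f_hat <- f_hat[ok]
  if (!length(e)) f_hat <- e <- 0
  switch(kind,
    linear = {
      l1 <- if (sum(e^2) > 0) sum(e * f_hat) / sum(e^2) else 0
      c(l1 = l1, l2 = 0)
    },
    hyperbolic = {
      i <- which.max(abs(e))
      h1 <- f_hat[i]
      if (abs(h1) < 1e-3) h1 <- 0.1
      emax <- max(abs(e), 1)
      c(h1 = h1, h2 = -2 / emax)
    },
    sigmoidal = {
      pos <- e > 0
      s1 <- if (any(pos)) f_hat[pos][which.min(e[pos])] else 0.5
      if (abs(s1) < 1e-3) s1 <- 0.5
      s2 <- if (any(pos)) stats::median(e[pos]) else 1
      c(s1 = s1, s2 = s2, s3 = 2)
    },
    bell = {
      i <- which.max(f_hat)
      b1 <- max(f_hat[i], 0.1)
      b4 <- if (length(e) && e[i] > 0) e[i] else max(stats::median(e[e > 0]), 1)
      c(b1 = b1, b2 = 1, b3 = 1, b4 = b4)
    })
}

## target value on the control curve, for derived-parameter targets
control_target_value <- function(kp, target) {
  switch(target,
         K = kp$K, tau = kp$tau, alpha = kp$alpha,
         v_tau = derived_kinetics(kp)$v_tau,
         v_m = derived_kinetics(kp)$v_m,
         lag = derived_kinetics(kp)$lag)
}

per_level_target_estimate <- function(fit, target) {
  switch(target,
         K = fit$kinetic_params$K,
         tau = fit$kinetic_params$tau,
         alpha = fit$kinetic_params$alpha,
         v_tau = fit$derived$v_tau,
         v_m = fit$derived$v_m,
         lag = fit$derived$lag)
}

#' Simultaneous time-effector fit of a panel of hemolysis curves
#'
#' Fits the whole panel of kinetic curves at once to the bivariate survival
#' surface: one shared control triple `(K, tau, alpha)` plus the
#' coefficients of the modifier functions attached to the perturbed
#' parameters, minimizing a single joint sum of squares. Relative to
#' fitting each curve separately and regressing the per-curve half-lives on
#' dose (see [fit_two_step()]), the simultaneous fit uses every observation
#' for every parameter, which narrows the confidence intervals of the
#' potency coefficients.
#'
#' @param data data frame with columns `time` (min), `response` (percent
#'   survival) and `effector` (level, in its declared units); a `replicate`
#'   column is allowed and ignored by the estimator.
#' @param preset modifier configuration name (see [effector_preset()]);
#'   ignored when `template` is supplied.
#' @param template an `effector_template` (from [effector_preset()] or
#'   hand-built with the same structure) naming, per perturbed parameter,
#'   the modifier kind and any coefficients fixed at known values.
#' @param free_l2 free the linear intercepts (default fixed at 0 so the
#'   control curve anchors the surface).
#' @param start optional named starting values, e.g.
#'   `c(tau = 70, tau_l1 = 0.01)`; modifier coefficients are named
#'   `<target>_<coefficient>`.
#' @param weights,level,control as in [fit_univariate()].
#' @return An `oxhlia_fit` (kind `"bivariate"`) additionally carrying
#'   `model` (the fitted [effector_model()]), `level_table` (per effector
#'   level: composed `m_K`, `m_tau`, `m_alpha` and the hemolysis delay
#'   `delta_t = m_tau - tau_C`), and `template`.
#' @examples
#' sc <- simulation_scenario(noise_sd = 0)
#' panel <- simulate_panel(sc)
#' fit <- fit_bivariate(panel)
#' coef(fit)
#' @export
fit_bivariate <- function(data, preset = "antioxidant-L", template = NULL,
                          free_l2 = FALSE, start = NULL, weights = NULL,
                          level = 0.95, control = list()) {
  req <- c("time", "response", "effector")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort_data("`data` must be a data frame with columns time, response, effector")
  }
  if (is.null(template)) {
    template <- effector_preset(preset, free_l2 = free_l2)
  }
  levels_e <- sort(unique(data$effector))
  if (length(levels_e) < 2) {
    abort_fit("identifiability: at least 2 distinct effector levels are required")
  }
  time <- data$time
  response <- data$response
  effector <- data$effector

  ## ---- parameter bookkeeping
  par_names <- c("K", "tau", "alpha")
  lower <- c(1e-6, 1e-6, 0.05)
  upper <- c(120, 10 * max(time, 1), 50)
  derived_target <- intersect(names(template$modifiers), c("v_m", "v_tau", "lag"))
  if (length(derived_target)) {
    lower[3] <- 1.01  # derived-parameter targets live in the sigmoidal regime
  }
  mod_info <- list()
  for (target in names(template$modifiers)) {
    spec <- template$modifiers[[target]]
    all_coefs <- modifier_coef_names(spec$kind)
    fixed <- spec$fixed
    free <- setdiff(all_coefs, names(fixed))
    cb <- coef_bounds(spec$kind)
    mod_info[[target]] <- list(kind = spec$kind, fixed = fixed, free = free)
    par_names <- c(par_names, paste(target, free, sep = "_"))
    lower <- c(lower, unname(cb$lower[free]))
    upper <- c(upper, unname(cb$upper[free]))
  }
  p <- length(par_names)
  if (nrow(data) <= p) {
    abort_fit(sprintf(
      "under-determined fit: %d observations for %d free parameters",
      nrow(data), p))
  }

  assemble <- function(par) {
    names(par) <- par_names
    mods <- list()
    for (target in names(mod_info)) {
      mi <- mod_info[[target]]
      coefs <- stats::setNames(numeric(0), character(0))
      if (length(mi$fixed)) coefs <- mi$fixed
      coefs[mi$free] <- par[paste(target, mi$free, sep = "_")]
      coefs <- coefs[modifier_coef_names(mi$kind)]
      mods[[target]] <- new_modifier(mi$kind, coefs)
    }
    effector_model(kinetic_params(par[["K"]], par[["tau"]], par[["alpha"]]),
                   mods)
  }
  predict_fn <- function(par) {
    bivariate_survival(time, effector, assemble(par))
  }

  ## ---- initialization: per-level univariate prefits
  prefits <- lapply(levels_e, function(lev) {
    idx <- effector == lev
    tryCatch(suppressWarnings(
      fit_univariate(time[idx], response[idx], control = control)),
      error = function(e) NULL)
  })
  names(prefits) <- as.character(levels_e)
  got <- !vapply(prefits, is.null, logical(1))
  ctl0 <- if (any(got)) {
    i0 <- which(got)[which.min(abs(levels_e[got]))]
    prefits[[i0]]$kinetic_params
  } else {
    initial_kinetic_guess(time, response)
  }
  start0 <- c(K = ctl0$K, tau = ctl0$tau, alpha = ctl0$alpha)
  for (target in names(mod_info)) {
    mi <- mod_info[[target]]
    theta_c <- control_target_value(ctl0, target)
    f_hat <- vapply(seq_along(levels_e), function(i) {
      if (!got[i] || is.na(theta_c) || theta_c == 0) return(NA_real_)
      per_level_target_estimate(prefits[[i]], target) / theta_c - 1
    }, numeric(1))
    coefs <- init_modifier_coefs(mi$kind, levels_e, f_hat)
    start0 <- c(start0, stats::setNames(coefs[mi$free],
                                        paste(target, mi$free, sep = "_")))
  }
  if (!is.null(start)) {
    known <- intersect(names(start), par_names)
    start0[known] <- start[known]
  }
  start0 <- pmin(pmax(start0[par_names], lower), upper)

  run <- run_nls(response, predict_fn, start0, lower, upper, weights, control)
  J <- numeric_jacobian(predict_fn, run$par)
  inf <- nls_inference(run$par, J, run$residuals, response, level)
  model <- assemble(run$par)

  level_params <- lapply(levels_e, function(lev) params_at_level(model, lev))
  level_table <- data.frame(
    effector = levels_e,
    m_K = vapply(level_params, `[[`, numeric(1), "K"),
    m_tau = vapply(level_params, `[[`, numeric(1), "tau"),
    m_alpha = vapply(level_params, `[[`, numeric(1), "alpha"))
  level_table$delta_t <- delta_t(level_table$m_tau, model$control$tau)

  fit <- new_oxhlia_fit(run, inf, kind = "bivariate", base = "eq5",
                        data = data,
                        extra = list(model = model, template = template,
                                     level_table = level_table,
                                     kinetic_params = model$control))
  if (!run$converged) {
    abort_convergence(sprintf(
      "simultaneous fit did not converge (optimizer: %s)", run$message),
      fit = fit)
  }
  ## structural-identifiability advisory: a modifier coefficient whose CI
  ## spans zero signals a nonsignificant perturbation term
  mod_pars <- setdiff(par_names, c("K", "tau", "alpha"))
  weak <- mod_pars[!inf$significant[mod_pars]]
  if (length(weak)) {
    warning(warningCondition(
      sprintf("modifier coefficient(s) not significant at alpha = %.2g: %s",
              1 - level, paste(weak, collapse = ", ")),
      class = c("oxhlia_identifiability_warning", "oxhlia_warning")))
  }
  fit
}

#' Two-step analysis: per-curve fits, then dose regression of the half-life
#'
#' The classical procedure the simultaneous fit replaces: each kinetic curve
#' is fitted separately, and the fitted half-lives are then regressed on the
#' effector level as `tau_hat(e) = tau_C * (1 + l1 * e)`. The second-stage
#' inference ignores the uncertainty structure of the first stage and uses
#' only one number per curve, so its confidence interval for the potency
#' slope `l1` is wider than the simultaneous one.
#'
#' @inheritParams fit_bivariate
#' @return A list with `l1`, `tau_C`, their standard errors and confidence
#'   half-widths (`l1_se`, `l1_ci`, ...), `dof`, and `per_level` (the
#'   first-stage half-life estimates).
#' @export
fit_two_step <- function(data, level = 0.95, control = list()) {
  req <- c("time", "response", "effector")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort_data("`data` must be a data frame with columns time, response, effector")
  }
  levels_e <- sort(unique(data$effector))
  if (length(levels_e) < 3) {
    abort_fit("the two-step regression needs at least 3 effector levels")
  }
  tau_hat <- vapply(levels_e, function(lev) {
    idx <- data$effector == lev
    suppressWarnings(
      fit_univariate(data$time[idx], data$response[idx],
                     control = control))$kinetic_params$tau
  }, numeric(1))
  tau0 <- tau_hat[which.min(abs(levels_e))]
  l10 <- if (sum(levels_e^2) > 0) {
    sum(levels_e * (tau_hat / tau0 - 1)) / sum(levels_e^2)
  } else 0
  predict_fn <- function(par) par[[1]] * (1 + par[[2]] * levels_e)
  run <- run_nls(tau_hat, predict_fn,
                 c(tau_C = tau0, l1 = l10),
                 lower = c(1e-6, -Inf), upper = c(Inf, Inf),
                 control = control)
  J <- numeric_jacobian(predict_fn, run$par)
  inf <- nls_inference(run$par, J, run$residuals, tau_hat, level)
  list(tau_C = run$par[["tau_C"]], l1 = run$par[["l1"]],
       tau_C_se = inf$std_errors[["tau_C"]], l1_se = inf$std_errors[["l1"]],
       tau_C_ci = inf$ci_halfwidths[["tau_C"]],
       l1_ci = inf$ci_halfwidths[["l1"]],
       dof = inf$dof, r2_adj = inf$r2_adj,
       per_level = data.frame(effector = levels_e, tau_hat = tau_hat))
}

#' Residual diagnostics
#'
#' Informational (never gating) summaries of the residual vector of a fit:
#' a Shapiro-Wilk normality test and the lag-1 autocorrelation. An all-zero
#' residual vector (perfect fit) is flagged degenerate instead of tested.
#'
#' @param residuals numeric residual vector, length >= 8.
#' @return A list with `n`, `shapiro_w`, `shapiro_p`, `lag1_autocorr` and
#'   `degenerate`.
#' @export
residual_diagnostics <- function(residuals) {
  if (!is.numeric(residuals) || length(residuals) < 8) {
    abort_data("at least 8 residuals are required for diagnostics")
  }
  if (all(residuals == 0)) {
    return(list(n = length(residuals), shapiro_w = NA_real_,
                shapiro_p = NA_real_, lag1_autocorr = NA_real_,
                degenerate = TRUE))
  }
  sw <- tryCatch(stats::shapiro.test(residuals),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  r <- residuals - mean(residuals)
  n <- length(r)
  lag1 <- sum(r[-1] * r[-n]) / sum(r^2)
  list(n = n, shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
       lag1_autocorr = lag1, degenerate = FALSE)
}

## ---- oxhlia_fit methods ----------------------------------------------------

#' Parameter table of a fit
#'
#' One row per parameter: estimate, standard error, 95% confidence
#' half-width, t value, p value and significance flag, mirroring the layout
#' of published kinetic tables.
#'
#' @param fit an `oxhlia_fit`.
#' @return A data frame.
#' @export
fit_parameter_table <- function(fit) {
  if (!inherits(fit, "oxhlia_fit")) abort_param("`fit` must be an oxhlia_fit")
  data.frame(parameter = names(fit$estimates),
             estimate = unname(fit$estimates),
             std_error = unname(fit$std_errors),
             ci_halfwidth = unname(fit$ci_halfwidths),
             t_value = unname(fit$t_values),
             p_value = unname(fit$p_values),
             significant = unname(fit$significant),
             row.names = NULL)
}

#' @export
as.data.frame.oxhlia_fit <- function(x, ...) fit_parameter_table(x)

#' @export
coef.oxhlia_fit <- function(object, ...) object$estimates

#' @export
confint.oxhlia_fit <- function(object, parm, level = NULL, ...) {
  est <- object$estimates
  ci <- object$ci_halfwidths
  out <- cbind(lower = est - ci, upper = est + ci)
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
predict.oxhlia_fit <- function(object, newdata = NULL, ...) {
  if (object$kind == "univariate") {
    t <- if (is.null(newdata)) object$data$time
         else if (is.data.frame(newdata)) newdata$time else newdata
    weibull_survival(t, object$kinetic_params)
  } else {
    nd <- if (is.null(newdata)) object$data else newdata
    bivariate_survival(nd$time, nd$effector, object$model)
  }
}

#' @export
print.oxhlia_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s survival-kinetics fit (%s base)\n",
              if (x$kind == "bivariate") "Simultaneous time-effector"
              else "Univariate", x$base))
  tab <- fit_parameter_table(x)
  tab[2:6] <- lapply(tab[2:6], signif, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("n = %d, dof = %d, SSE = %.6g, R2_adj = %.6g\n",
              x$n_obs, x$dof, x$sse, x$r2_adj))
  cat(sprintf("F = %.6g (p = %.3g), converged in %d iterations\n",
              x$f_statistic, x$f_pvalue, x$iterations))
  invisible(x)
}

#' @export
summary.oxhlia_fit <- function(object, ...) {
  print(object)
  d <- residual_diagnostics(object$residuals)
  if (d$degenerate) {
    cat("Residuals: degenerate (perfect fit)\n")
  } else {
    cat(sprintf("Residuals: Shapiro-Wilk p = %.3g, lag-1 autocorrelation = %.3g\n",
                d$shapiro_p, d$lag1_autocorr))
  }
  invisible(object)
}

#' @export
plot.oxhlia_fit <- function(x, ...) {
  d <- x$data
  if (x$kind == "univariate") {
    graphics::plot(d$time, d$response, xlab = "time (min)",
                   ylab = "survival (%)", ...)
    tt <- seq(min(d$time), max(d$time), length.out = 200)
    graphics::lines(tt, weibull_survival(tt, x$kinetic_params))
  } else {
    levs <- sort(unique(d$effector))
    cols <- grDevices::hcl.colors(length(levs), "viridis")
    graphics::plot(d$time, d$response, type = "n", xlab = "time (min)",
                   ylab = "survival (%)", ...)
    tt <- seq(min(d$time), max(d$time), length.out = 200)
    for (i in seq_along(levs)) {
      idx <- d$effector == levs[i]
      graphics::points(d$time[idx], d$response[idx], col = cols[i])
      graphics::lines(tt, bivariate_survival(tt, levs[i], x$model),
                      col = cols[i])
    }
  }
  invisible(x)
}
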