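test_that("a noiseless curve is recovered exactly, in every parameterization", {
  p <- ref_control()
  t <- seq(0, 180, length.out = 13)
  y <- weibull_survival(t, p)
  for (base in c("eq5", "vm", "vtau", "lambda")) {
    fit <- fit_univariate(t, y, base = base)
    kp <- fit$kinetic_params
    expect_equal(kp$K, p$K, tolerance = 1e-6)
    expect_equal(kp$tau, p$tau, tolerance = 1e-6)
    expect_equal(kp$alpha, p$alpha, tolerance = 1e-6)
    expect_equal(fit$r2_adj, 1, tolerance = 1e-9)
    expect_true(all(fit$std_errors < 1e-6))
  }
})

test_that("the four base forms reach the same optimum on noisy data", {
  set.seed(41)
  for (i in 1:5) {
    p <- random_params(1, alpha_min = 2, alpha_max = 10)[[1]]
    t <- seq(0, 3 * p$tau, length.out = 19)
    y <- weibull_survival(t, p) + rnorm(19, 0, 1.5)
    fits <- lapply(c("eq5", "vm", "vtau", "lambda"), function(b) {
      suppressWarnings(fit_univariate(t, y, base = b))
    })
    sse <- vapply(fits, `[[`, numeric(1), "sse")
    expect_lt(diff(range(sse)) / min(sse), 1e-6)
    # parameters agree through the closed-form mapping
    taus <- vapply(fits, function(f) f$kinetic_params$tau, numeric(1))
    expect_lt(diff(range(taus)) / min(taus), 1e-5)
    # and the explicit parameters equal the derived ones of the native fit
    d <- derived_kinetics(fits[[1]]$kinetic_params)
    expect_equal(fits[[2]]$estimates[["v_m"]], d$v_m, tolerance = 1e-5)
    expect_equal(fits[[3]]$estimates[["v_tau"]], d$v_tau, tolerance = 1e-5)
    expect_equal(fits[[4]]$estimates[["lag"]], d$lag, tolerance = 1e-4)
  }
})

test_that("true parameters fall inside the 95% intervals on a seeded noisy curve", {
  p <- ref_control()
  cur <- noisy_curve(seed = 42, p = p, times = seq(0, 180, length.out = 19))
  fit <- suppressWarnings(fit_univariate(cur$time, cur$response))
  ci <- confint(fit)
  expect_gt(p$K, ci["K", "lower"]);      expect_lt(p$K, ci["K", "upper"])
  expect_gt(p$tau, ci["tau", "lower"]);  expect_lt(p$tau, ci["tau", "upper"])
  expect_gt(p$alpha, ci["alpha", "lower"]); expect_lt(p$alpha, ci["alpha", "upper"])
  # the ci-halfwidth / SE / t-quantile relation holds exactly
  expect_equal(unname(fit$ci_halfwidths),
               unname(qt(0.975, fit$dof) * fit$std_errors))
  expect_equal(fit$dof, fit$n_obs - 3)
})

test_that("degenerate and under-determined inputs raise classed fit errors", {
  expect_error(fit_univariate(0:10, rep(50, 11)), class = "oxhlia_fit_error")
  expect_error(fit_univariate(0:2, c(100, 80, 60)), class = "oxhlia_fit_error")
  panel <- noisy_panel(seed = 1)
  expect_error(fit_bivariate(panel[panel$effector == 0, ]),
               class = "oxhlia_fit_error")
})

test_that("linearized inference matches closed-form OLS on straight-line data", {
  set.seed(43)
  x <- seq(0, 10, length.out = 12)
  y <- 3 + 2 * x + rnorm(12, 0, 0.5)
  lmfit <- lm(y ~ x)
  J <- cbind(intercept = rep(1, 12), slope = x)
  est <- setNames(coef(lmfit), c("intercept", "slope"))
  inf <- nls_inference(est, J, residuals(lmfit), y)
  sm <- summary(lmfit)
  expect_equal(unname(inf$std_errors), unname(sm$coefficients[, "Std. Error"]),
               tolerance = 1e-10)
  expect_equal(inf$r2, sm$r.squared, tolerance = 1e-10)
  # this package counts every fitted parameter in the adjustment term
  expect_equal(inf$r2_adj, 1 - (1 - sm$r.squared) * (12 - 1) / (12 - 2 - 1),
               tolerance = 1e-10)
  expect_equal(inf$f_statistic, unname(sm$fstatistic["value"]),
               tolerance = 1e-10)
})

test_that("a perfect fit reports zero errors and unit determination", {
  x <- seq_len(10)
  J <- cbind(a = rep(1, 10), b = x)
  inf <- nls_inference(c(a = 1, b = 2), J, rep(0, 10), 1 + 2 * x)
  expect_true(all(inf$std_errors == 0))
  expect_equal(inf$r2_adj, 1)
  expect_equal(inf$f_statistic, Inf)
})

test_that("rank deficiency is reported with the unidentifiable direction", {
  J <- cbind(a = rep(1, 10), b = rep(2, 10))  # collinear columns
  err <- tryCatch(nls_inference(c(a = 1, b = 1), J, rnorm(10), rnorm(10)),
                  error = identity)
  expect_s3_class(err, "oxhlia_fit_error")
  expect_match(conditionMessage(err), "not identifiable")
})

test_that("reported standard errors agree with Monte-Carlo spread", {
  p <- ref_control()
  t <- seq(0, 180, by = 10)
  truth <- weibull_survival(t, p)
  set.seed(44)
  tau_hat <- se_tau <- numeric(200)
  for (i in 1:200) {
    y <- truth + rnorm(length(t), 0, 1.5)
    f <- suppressWarnings(fit_univariate(t, y))
    tau_hat[i] <- f$kinetic_params$tau
    se_tau[i] <- f$std_errors[["tau"]]
  }
  expect_lt(abs(mean(se_tau) - sd(tau_hat)) / sd(tau_hat), 0.20)
})

test_that("noiseless panels from any effector model are recovered exactly", {
  # linear antioxidant surface
  panel <- simulate_panel(simulation_scenario(noise_sd = 0))
  fit <- fit_bivariate(panel)
  expect_equal(unname(coef(fit)), c(100, 70.5, 4.83, 0.0086, 0.0121),
               tolerance = 1e-5)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-9)

  # saturating prooxidant surface: hyperbolic on tau, linear on alpha
  pro <- effector_model(kinetic_params(100, 120, 5),
                        list(tau = hyperbolic_modifier(-0.6, -0.03),
                             alpha = linear_modifier(0.004)))
  panel2 <- simulate_panel(simulation_scenario(
    model = pro, effector_levels = seq(0, 100, by = 20), noise_sd = 0))
  fit2 <- fit_bivariate(panel2, preset = "prooxidant-H")
  expect_equal(unname(coef(fit2)[c("K", "tau", "alpha")]), c(100, 120, 5),
               tolerance = 1e-5)
  expect_equal(fit2$estimates[["tau_h1"]], -0.6, tolerance = 1e-4)
  expect_equal(fit2$estimates[["tau_h2"]], -0.03, tolerance = 1e-4)
  expect_equal(fit2$estimates[["alpha_l1"]], 0.004, tolerance = 1e-4)
})

test_that("a bell perturbation of the half-life rate is recovered from a panel", {
  temp <- effector_model(kinetic_params(100, 90, 6),
                         list(v_tau = bell_modifier(1.2, 2, 1.5, 30),
                              alpha = linear_modifier(-0.004)))
  panel <- simulate_panel(simulation_scenario(
    model = temp, effector_levels = c(15, 20, 25, 30, 35, 40, 45),
    noise_sd = 0))
  fit <- fit_bivariate(panel, preset = "temperature-B")
  expect_equal(unname(coef(fit)[c("K", "tau", "alpha")]), c(100, 90, 6),
               tolerance = 1e-4)
  expect_equal(fit$estimates[["v_tau_b1"]], 1.2, tolerance = 1e-3)
  expect_equal(fit$estimates[["v_tau_b4"]], 30, tolerance = 1e-3)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-8)
})

test_that("true coefficients fall inside the joint 95% intervals on a seeded panel", {
  panel <- noisy_panel(seed = 45)
  fit <- suppressWarnings(fit_bivariate(panel))
  ci <- confint(fit)
  truth <- c(K = 100, tau = 70.5, alpha = 4.83, tau_l1 = 0.0086,
             alpha_l1 = 0.0121)
  for (nm in names(truth)) {
    expect_gt(truth[[nm]], ci[nm, "lower"])
    expect_lt(truth[[nm]], ci[nm, "upper"])
  }
  # per-level composed parameters and hemolysis delays are reported
  expect_equal(nrow(fit$level_table), 6)
  expect_equal(fit$level_table$delta_t[1], 0, tolerance = 1e-9)
  expect_true(all(diff(fit$level_table$m_tau) > 0))
})

test_that("weak modifier coefficients trigger an identifiability warning", {
  # alpha modifier slope too small to detect at this noise level
  weak <- effector_model(kinetic_params(100, 70.5, 4.83),
                         list(tau = linear_modifier(0.0086),
                              alpha = linear_modifier(1e-5)))
  panel <- simulate_panel(simulation_scenario(model = weak, noise_sd = 2,
                                              seed = 46))
  expect_warning(fit_bivariate(panel),
                 class = "oxhlia_identifiability_warning")
})

test_that("the two-step procedure reproduces the slope but needs 3+ levels", {
  panel <- simulate_panel(simulation_scenario(noise_sd = 0))
  ts <- fit_two_step(panel)
  expect_equal(ts$l1, 0.0086, tolerance = 1e-5)
  expect_equal(ts$tau_C, 70.5, tolerance = 1e-4)
  expect_error(fit_two_step(panel[panel$effector <= 25, ]),
               class = "oxhlia_fit_error")
})

test_that("residual diagnostics summarize normality and autocorrelation", {
  set.seed(47)
  d <- residual_diagnostics(rnorm(100))
  expect_gt(d$shapiro_p, 0.05)
  expect_false(d$degenerate)
  alt <- rep(c(1, -1), 20)
  expect_equal(residual_diagnostics(alt)$lag1_autocorr, -39 / 40,
               tolerance = 1e-12)
  expect_true(residual_diagnostics(rep(0, 12))$degenerate)
  expect_error(residual_diagnostics(rnorm(5)), class = "oxhlia_data_error")
})

test_that("fit accessors expose a publication-style parameter table", {
  panel <- noisy_panel(seed = 48)
  fit <- suppressWarnings(fit_bivariate(panel))
  tab <- fit_parameter_table(fit)
  expect_named(tab, c("parameter", "estimate", "std_error", "ci_halfwidth",
                      "t_value", "p_value", "significant"))
  expect_identical(as.data.frame(fit), tab)
  expect_equal(unname(coef(fit)), tab$estimate)
  pred <- predict(fit)
  expect_equal(length(pred), nrow(panel))
  expect_output(print(fit), "R2_adj")
})
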