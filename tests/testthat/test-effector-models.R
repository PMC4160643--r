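test_that("modifier shapes evaluate their anchor points", {
  expect_equal(evaluate_modifier(linear_modifier(0.0086), 0), 0)
  expect_equal(evaluate_modifier(linear_modifier(0.0086), 125), 1.075)
  # hyperbolic asymptote at large e
  expect_equal(evaluate_modifier(hyperbolic_modifier(2, -0.5), 1e6), 2)
  # sigmoidal half-effect at e = s2, exactly
  expect_identical(evaluate_modifier(sigmoidal_modifier(3, 40, 2.5), 40), 3 / 2)
  # bell maximum b1 attained at e = b4
  expect_equal(evaluate_modifier(bell_modifier(1.8, 2, 1.5, 30), 30), 1.8)
})

test_that("modifier domains are enforced", {
  expect_error(evaluate_modifier(linear_modifier(1), -1),
               class = "oxhlia_effector_error")
  expect_error(evaluate_modifier(sigmoidal_modifier(1, 10, 2), 0),
               class = "oxhlia_effector_error")
  expect_error(evaluate_modifier(bell_modifier(1, 1, 1, 10), -5),
               class = "oxhlia_effector_error")
  expect_error(sigmoidal_modifier(1, -10, 2), class = "oxhlia_parameter_error")
  expect_error(bell_modifier(1, 0, 1, 10), class = "oxhlia_parameter_error")
})

test_that("bell modifier peaks at b4 over a dense grid", {
  set.seed(21)
  for (i in 1:10) {
    b <- c(runif(1, 0.5, 3), runif(1, 0.5, 4), runif(1, 0.5, 4),
           runif(1, 5, 80))
    spec <- bell_modifier(b[1], b[2], b[3], b[4])
    e <- seq(b[4] / 50, b[4] * 4, length.out = 20000)
    f <- evaluate_modifier(spec, e)
    expect_lt(abs(e[which.max(f)] - b[4]), b[4] * 4 / 1000)
    expect_lte(max(f), b[1] + 1e-12)
  }
})

test_that("parameter composition follows m = theta_C (1 + f(e))", {
  expect_equal(modified_parameter(70.5, linear_modifier(0.0086), 125),
               146.2875, tolerance = 1e-10)
  expect_equal(modified_parameter(4.83, linear_modifier(0.0121), 100),
               10.6743, tolerance = 1e-10)
  # f(e) = 0 leaves the control untouched
  expect_identical(modified_parameter(5.5, linear_modifier(0), 80), 5.5)
  expect_warning(modified_parameter(10, linear_modifier(-1), 2),
                 class = "oxhlia_domain_warning")
})

test_that("the bivariate surface equals compose-then-evaluate pointwise", {
  model <- trolox_dose_model()
  set.seed(22)
  for (i in 1:50) {
    t <- runif(1, 0, 250)
    e <- runif(1, 0, 125)
    p <- params_at_level(model, e)
    expect_equal(bivariate_survival(t, e, model), weibull_survival(t, p),
                 tolerance = 1e-12)
    # half-life identity holds pointwise in e
    expect_equal(bivariate_survival(p$tau, e, model), p$K / 2,
                 tolerance = 1e-9)
  }
  # frozen scalar oracle, computed by independent plain arithmetic:
  # m_tau = 70.5*(1+0.0086*125), m_alpha = 4.83*(1+0.0121*125)
  expect_equal(bivariate_survival(150, 125, model), 39.081424,
               tolerance = 1e-6)
})

test_that("identity-baseline modifiers preserve the control curve at e = 0", {
  t <- seq(0, 200, by = 5)
  ctl <- kinetic_params(100, 70.5, 4.83)
  model <- effector_model(ctl, list(tau = linear_modifier(0.0086),
                                    alpha = linear_modifier(0.0121),
                                    K = hyperbolic_modifier(-0.3, -0.1)))
  expect_equal(bivariate_survival(t, 0, model), weibull_survival(t, ctl),
               tolerance = 1e-12)
})

test_that("derived-parameter targets perturb the implied half-life consistently", {
  ctl <- kinetic_params(100, 70.5, 4.83)
  model <- effector_model(ctl, list(v_tau = bell_modifier(1.5, 2, 1, 30),
                                    alpha = linear_modifier(-0.005)))
  e <- 30
  p <- params_at_level(model, e)
  d0 <- derived_kinetics(ctl)
  expect_equal(derived_kinetics(p)$v_tau,
               d0$v_tau * (1 + evaluate_modifier(model$modifiers$v_tau, e)),
               tolerance = 1e-10)
  # only one half-life-determining target may be modified
  expect_error(
    effector_model(ctl, list(tau = linear_modifier(0.01),
                             v_tau = linear_modifier(0.01))),
    class = "oxhlia_parameter_error")
})

test_that("presets wire the documented modifier shapes", {
  px <- effector_preset("antioxidant-L")
  expect_setequal(names(px$modifiers), c("tau", "alpha"))
  expect_equal(px$modifiers$tau$fixed, c(l2 = 0))
  expect_equal(effector_preset("antioxidant-L", free_l2 = TRUE)$modifiers$tau$fixed,
               c())
  expect_equal(effector_preset("prooxidant-H")$modifiers$tau$kind, "hyperbolic")
  expect_equal(effector_preset("surfactant")$modifiers$alpha$kind, "hyperbolic")
  expect_equal(effector_preset("temperature-B")$modifiers$v_tau$kind, "bell")
})
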