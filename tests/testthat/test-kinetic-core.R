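test_that("survival evaluates its defining identities and anchor points", {
  p <- ref_control()
  expect_equal(weibull_survival(0, p), p$K)
  expect_equal(weibull_survival(p$tau, p), p$K / 2)
  # two half-lives of first-order decay
  expect_equal(weibull_survival(20, kinetic_params(100, 10, 1)), 25)
  # scalar anchor evaluated with independent high-precision arithmetic
  expect_equal(weibull_survival(90, p), 8.297242, tolerance = 1e-6)
  # t = 0 with alpha < 1 returns K by continuity
  expect_equal(weibull_survival(0, kinetic_params(100, 50, 0.5)), 100)
})

test_that("invalid parameters and times raise parameter-domain errors", {
  expect_error(kinetic_params(-1, 10, 2), class = "oxhlia_parameter_error")
  expect_error(kinetic_params(100, 0, 2), class = "oxhlia_parameter_error")
  expect_error(kinetic_params(100, 10, NA), class = "oxhlia_parameter_error")
  expect_error(weibull_survival(-5, ref_control()),
               class = "oxhlia_parameter_error")
  expect_error(hemolysis_rate(0, kinetic_params(100, 50, 0.5)),
               class = "oxhlia_parameter_error")
})

test_that("half-life identity and exponential reduction hold over random params", {
  set.seed(11)
  for (p in random_params(25, alpha_min = 0.3)) {
    expect_lt(abs(weibull_survival(p$tau, p) - p$K / 2), 1e-9)
  }
  # alpha = 1 reduces to first-order decay K * 2^(-t/tau)
  t <- seq(0, 300, by = 7.5)
  for (tau in c(12, 68.12, 140)) {
    p <- kinetic_params(100, tau, 1)
    expect_equal(weibull_survival(t, p), 100 * 2^(-t / tau), tolerance = 1e-9)
  }
})

test_that("survival is non-increasing and strictly decreasing past zero", {
  set.seed(12)
  for (p in random_params(10, alpha_min = 0.4)) {
    t <- seq(0, 3 * p$tau, length.out = 500)
    s <- weibull_survival(t, p)
    expect_true(all(diff(s) <= 0))
    # strictly decreasing over the active window (outside it the curve is
    # flat at machine precision: ~K near 0, ~0 far past tau)
    keep <- s < p$K * (1 - 1e-9) & s > p$K * 1e-9
    expect_true(all(diff(s[keep]) < 0))
  }
})

test_that("derived parameters reproduce the published trolox table", {
  ref <- trolox_kinetics()
  for (i in seq_len(nrow(ref))) {
    d <- derived_kinetics(kinetic_params(ref$K[i], ref$tau[i], ref$alpha[i]))
    expect_lt(abs(d$v_tau - ref$v_tau[i]), 0.02)
    expect_lt(abs(d$v_m - ref$v_m[i]), 0.02)
    expect_lt(abs(d$lag - ref$lag[i]), 0.05)
  }
})

test_that("derived parameters respect their ordering and domain invariants", {
  set.seed(13)
  for (p in random_params(30, alpha_min = 1.05)) {
    d <- derived_kinetics(p)
    expect_true(all(d$defined))
    expect_gt(d$v_tau, 0)
    expect_gte(d$v_m, d$v_tau)
    expect_gte(d$lag, 0)
    expect_lt(d$lag, p$tau)
  }
})

test_that("alpha <= 1 yields v_tau only, with explicit undefined markers", {
  d <- derived_kinetics(kinetic_params(100, 100, 1))
  expect_equal(d$v_tau, 100 * log(2) / 200, tolerance = 1e-12)
  expect_true(is.na(d$v_m) && is.na(d$lag) && is.na(d$t_star))
  expect_equal(unname(d$defined), c(TRUE, FALSE, FALSE, FALSE))
  # report generation stays total
  expect_output(print(d), "undefined")
})

test_that("maximum rate and its location match a dense finite-difference oracle", {
  set.seed(14)
  for (p in random_params(8, alpha_min = 1.3, alpha_max = 12)) {
    d <- derived_kinetics(p)
    t <- seq(1e-4, 4 * p$tau, length.out = 40001)
    s <- weibull_survival(t, p)
    rate <- -diff(s) / diff(t)
    tm <- (t[-1] + t[-length(t)]) / 2
    expect_equal(max(rate), d$v_m, tolerance = 1e-4)
    expect_lt(abs(tm[which.max(rate)] - d$t_star), 2 * diff(t)[1])
    # rate at the half-life matches v_tau
    expect_equal(hemolysis_rate(p$tau, p), d$v_tau, tolerance = 1e-12)
    i_tau <- which.min(abs(tm - p$tau))
    expect_equal(rate[i_tau], d$v_tau, tolerance = 1e-3)  # midpoint offset
  }
})

test_that("the three explicit-parameter forms round-trip to the native form", {
  p <- ref_control()
  d <- derived_kinetics(p)
  for (t in c(10, 68.12, 150)) {
    expect_equal(survival_from_vtau(t, p$K, d$v_tau, p$alpha),
                 weibull_survival(t, p), tolerance = 1e-12)
    expect_equal(survival_from_vm(t, p$K, d$v_m, p$alpha),
                 weibull_survival(t, p), tolerance = 1e-12)
    expect_equal(survival_from_lambda(t, p$K, d$lag, p$alpha),
                 weibull_survival(t, p), tolerance = 1e-12)
  }
  expect_equal(survival_from_vtau(0, 100, 2.3, 4.59), 100)

  set.seed(15)
  t <- seq(0, 350, by = 3.5)
  for (p in random_params(20, alpha_min = 1.05)) {
    d <- derived_kinetics(p)
    base <- weibull_survival(t, p)
    for (s in list(survival_from_vm(t, p$K, d$v_m, p$alpha),
                   survival_from_vtau(t, p$K, d$v_tau, p$alpha),
                   survival_from_lambda(t, p$K, d$lag, p$alpha))) {
      expect_equal(s, base, tolerance = 1e-8)
    }
  }
})

test_that("explicit forms refuse their domain violations", {
  expect_error(survival_from_vm(10, 100, 2, 0.9), class = "oxhlia_parameter_error")
  expect_error(survival_from_lambda(10, 100, 40, 1), class = "oxhlia_parameter_error")
  expect_error(tau_from_vtau(100, -2, 4), class = "oxhlia_parameter_error")
})

test_that("classical shape/scale parameters map onto the half-life form", {
  a <- 4.59; b <- 75
  p <- kinetic_params_from_shape_scale(a, b)
  expect_equal(p$alpha, a)
  expect_equal(p$tau, b * log(2)^(1 / a))
  t <- seq(0, 200, by = 10)
  expect_equal(weibull_survival(t, p), 100 * exp(-(t / b)^a), tolerance = 1e-12)
})
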