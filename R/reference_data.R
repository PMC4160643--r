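#' Published trolox reference kinetics
#'
#' Per-curve kinetic parameter estimates for sheep-erythrocyte hemolysis
#' (40 mM AAPH, 37 C, plate format, readings every 10 min) inhibited by the
#' reference antioxidant trolox at 0--125 uM, as published for this assay.
#' Each row is one dose: the fitted `(K, tau, alpha)` triple, the adjusted
#' R-squared of that fit, and the printed derived parameters (`v_tau`,
#' `v_m`, `lag`). Used as the canonical worked example, as the default
#' generating conditions of the synthetic-panel module, and as the numerical
#' anchor that [derived_kinetics()] is validated against.
#'
#' @return A data frame with columns `trolox_uM`, `K`, `tau`, `alpha`,
#'   `r2_adj`, `v_tau`, `v_m`, `lag`.
#' @seealso [trolox_dose_model()]
#' @examples
#' ref <- trolox_kinetics()
#' derived_kinetics(kinetic_params(ref$K[1], ref$tau[1], ref$alpha[1]))
#' @export
trolox_kinetics <- function() {
  data.frame(
    trolox_uM = c(0, 25, 50, 75, 100, 125),
    K = c(100, 100, 100, 100, 100, 100),
    tau = c(68.12, 86.05, 102.96, 117.26, 130.76, 144.26),
    alpha = c(4.59, 6.44, 8.26, 10.14, 11.20, 10.86),
    r2_adj = c(0.9992, 0.9993, 0.9984, 0.9988, 0.9987, 0.9971),
    v_tau = c(2.34, 2.59, 2.78, 3.00, 2.97, 2.61),
    v_m = c(2.35, 2.63, 2.85, 3.09, 3.06, 2.69),
    lag = c(39.92, 59.87, 78.16, 94.04, 107.22, 117.51)
  )
}

#' Published trolox time-dose model
#'
#' The simultaneous (bivariate) time-dose model estimated from the same
#' trolox series as [trolox_kinetics()]: control curve
#' `(K, tau, alpha) = (100, 70.5, 4.83)` with linear dose modifiers on the
#' half-life (`l1 = 0.0086` per uM) and on the shape (`l1 = 0.0121` per uM),
#' intercepts fixed at zero. This is the default generating model of
#' [simulation_scenario()].
#'
#' @return An [effector_model()].
#' @export
trolox_dose_model <- function() {
  effector_model(kinetic_params(K = 100, tau = 70.5, alpha = 4.83),
                 list(tau = linear_modifier(0.0086),
                      alpha = linear_modifier(0.0121)))
}
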