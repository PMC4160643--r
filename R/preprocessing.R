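#' Percent survival from optical-density readings
#'
#' Converts turbidity readings of an erythrocyte suspension to the percent
#' of the population still intact:
#' \deqn{P = 100\,(n_t - n_{max}) / (n_0 - n_{max})}
#' where `n_t` is the reading at time `t`, `n_0` the reading at the start of
#' the reaction and `n_max` the reading of the complete-hemolysis control
#' (water-lysed wells). `P(n_0) = 100`, `P(n_max) = 0`. The transform is
#' invariant to a common additive offset of all three readings. Values
#' outside `[0, 100]` (measurement noise) are retained, not clipped:
#' clipping would bias the fitted asymptote.
#'
#' @param n_t optical density at time t (vectorized).
#' @param n_0 optical density at the start of the series.
#' @param n_max optical density of complete hemolysis.
#' @return Percent survival.
#' @export
survival_percent <- function(n_t, n_0, n_max) {
  if (!is.numeric(n_t) || !is.numeric(n_0) || !is.numeric(n_max)) {
    abort_data("optical densities must be numeric")
  }
  if (any(n_0 == n_max)) {
    abort_data("degenerate series: n_0 equals n_max (no dynamic range)")
  }
  100 * (n_t - n_max) / (n_0 - n_max)
}

#' Normalize a response to its maximum
#'
#' `P = 100 * R / R_max`, the normalization applied to raw responses before
#' fitting so that sample-to-sample variation (dilution, cell count) scales
#' out. Normalization changes only the scale of the asymptote `K`; the
#' half-life and shape are unaffected.
#'
#' @param R response value(s).
#' @param R_max maximum attainable response, `> 0`.
#' @return Percent of maximum.
#' @export
normalize_response <- function(R, R_max) {
  if (!is.numeric(R) || !is.numeric(R_max)) {
    abort_data("responses must be numeric")
  }
  if (any(R_max <= 0)) {
    abort_data("degenerate series: R_max must be strictly positive")
  }
  100 * R / R_max
}

#' Hemolysis delay
#'
#' The classical single-number assay endpoint: the delay of the hemolytic
#' half-life caused by a sample relative to the control,
#' `delta_t = tau_S - tau_C` (minutes). Positive values mean protection
#' (antioxidant), negative values acceleration (prooxidant). Both half-lives
#' must come from fits on the same normalization scale.
#'
#' @param tau_s sample half-life, minutes.
#' @param tau_c control half-life, minutes.
#' @return Delay in minutes (vectorized).
#' @export
delta_t <- function(tau_s, tau_c) {
  if (!is.numeric(tau_s) || !is.numeric(tau_c)) {
    abort_data("half-lives must be numeric")
  }
  tau_s - tau_c
}
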