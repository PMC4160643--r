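#' Define a synthetic time-effector panel scenario
#'
#' Describes the experimental design a simulated hemolysis panel should
#' emulate: the generating time-effector model, the sampling grid, the
#' additive Gaussian noise on the percent-survival scale, the number of
#' replicate plates and the RNG seed. The defaults reproduce the standard
#' plate-format trolox study design: optical readings every 10 min for
#' 3 h, doses 0 to 125 uM in 25 uM steps, noise SD 1.5 percentage points,
#' and the published trolox time-dose model as ground truth.
#'
#' @param model generating [effector_model()] (default [trolox_dose_model()]).
#' @param time_grid strictly increasing observation times, minutes.
#' @param effector_levels effector levels to simulate.
#' @param noise_sd additive Gaussian SD on the percent scale (`>= 0`).
#' @param replicates number of replicate series per level.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(model = trolox_dose_model(),
                                time_grid = seq(0, 180, by = 10),
                                effector_levels = seq(0, 125, by = 25),
                                noise_sd = 1.5, replicates = 1,
                                seed = NULL) {
  if (!inherits(model, "effector_model")) {
    abort_param("`model` must be an effector_model")
  }
  if (!is.numeric(time_grid) || any(diff(time_grid) <= 0) || any(time_grid < 0)) {
    abort_param("`time_grid` must be strictly increasing non-negative times")
  }
  if (!is.numeric(effector_levels) || !length(effector_levels)) {
    abort_param("`effector_levels` must be a non-empty numeric vector")
  }
  check_number(noise_sd, "noise_sd", positive = FALSE)
  if (noise_sd < 0) abort_param("`noise_sd` must be >= 0")
  check_number(replicates, "replicates")
  structure(list(model = model, time_grid = time_grid,
                 effector_levels = effector_levels, noise_sd = noise_sd,
                 replicates = as.integer(replicates), seed = seed),
            class = "simulation_scenario")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a time-effector survival panel
#'
#' Generates percent-survival readings on the scenario's grid as the model
#' surface plus homoscedastic Gaussian noise (matching the unweighted
#' least-squares assumption of the fitting module). Negative or >100
#' simulated percentages are retained, consistent with the no-clipping rule
#' of the preprocessing arithmetic. The generating truth travels with the
#' data: the returned panel carries a `ground_truth` attribute holding the
#' exact model, the noiseless surface and the composed per-level
#' parameters, so tests and demonstrations never need to re-fit to know
#' the truth.
#'
#' @param scenario a [simulation_scenario()].
#' @return A data frame (class `oxhlia_panel`) with columns `time`,
#'   `effector`, `replicate`, `response`, and attribute `ground_truth`
#'   (list: `model`, `surface`, `level_params`, `noise_sd`, `seed`).
#' @examples
#' panel <- simulate_panel(simulation_scenario(noise_sd = 0))
#' head(panel)
#' @export
simulate_panel <- function(scenario) {
  if (!inherits(scenario, "simulation_scenario")) {
    abort_param("`scenario` must be a simulation_scenario")
  }
  grid <- expand.grid(time = scenario$time_grid,
                      effector = scenario$effector_levels,
                      replicate = seq_len(scenario$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  surface <- bivariate_survival(grid$time, grid$effector, scenario$model)
  noise <- with_seed(scenario$seed,
                     stats::rnorm(nrow(grid), 0, scenario$noise_sd))
  if (scenario$noise_sd == 0) noise <- numeric(nrow(grid))
  panel <- data.frame(time = grid$time, effector = grid$effector,
                      replicate = grid$replicate,
                      response = surface + noise)
  levs <- sort(unique(scenario$effector_levels))
  lp <- do.call(rbind, lapply(levs, function(lev) {
    p <- params_at_level(scenario$model, lev)
    data.frame(effector = lev, m_K = p$K, m_tau = p$tau, m_alpha = p$alpha)
  }))
  attr(panel, "ground_truth") <- list(model = scenario$model,
                                      surface = surface,
                                      level_params = lp,
                                      noise_sd = scenario$noise_sd,
                                      seed = scenario$seed)
  class(panel) <- c("oxhlia_panel", "data.frame")
  panel
}

#' Ground truth of a simulated panel
#'
#' @param panel an `oxhlia_panel` from [simulate_panel()].
#' @return The `ground_truth` attribute (generating model, noiseless
#'   surface, per-level composed parameters).
#' @export
ground_truth <- function(panel) {
  gt <- attr(panel, "ground_truth")
  if (is.null(gt)) abort_param("`panel` carries no ground-truth ledger")
  gt
}

#' Simulate an optical-density plate panel
#'
#' Maps a simulated percent-survival panel onto the optical-density scale
#' of a turbidity plate reader: `od = od_lysed + P/100 * (od_baseline -
#' od_lysed)`, where `od_baseline` is the reading of an intact suspension
#' and `od_lysed` that of the water-lysed complete-hemolysis control.
#' Noise is applied on the percent scale before the mapping, so
#' [survival_percent()] applied to the output with the same two reference
#' densities recovers the percent panel exactly (noisy or not), making the
#' preprocessing arithmetic testable end to end.
#'
#' @param scenario a [simulation_scenario()].
#' @param od_baseline optical density at the start of the reaction.
#' @param od_lysed optical density of complete hemolysis (must differ from
#'   `od_baseline`).
#' @return A data frame like [simulate_panel()] but with an `od` column in
#'   place of `response`; attributes `ground_truth`, `od_baseline`,
#'   `od_lysed`.
#' @export
simulate_od_panel <- function(scenario, od_baseline = 0.80, od_lysed = 0.30) {
  check_number(od_baseline, "od_baseline", positive = FALSE)
  check_number(od_lysed, "od_lysed", positive = FALSE)
  if (od_baseline == od_lysed) {
    abort_data("degenerate OD range: od_baseline equals od_lysed")
  }
  panel <- simulate_panel(scenario)
  od <- od_lysed + panel$response / 100 * (od_baseline - od_lysed)
  out <- data.frame(time = panel$time, effector = panel$effector,
                    replicate = panel$replicate, od = od)
  attr(out, "ground_truth") <- attr(panel, "ground_truth")
  attr(out, "od_baseline") <- od_baseline
  attr(out, "od_lysed") <- od_lysed
  class(out) <- c("oxhlia_panel", "data.frame")
  out
}
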