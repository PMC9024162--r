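#' Viable islet volume fraction
#'
#' Percentage of the islet volume whose steady-state local oxygen partial
#' pressure is at or above the critical survival pressure `p_crit`
#' (0.07 mmHg by default). The crossing radius is located by linear
#' interpolation of the radial profile between cell centers, so the
#' percentage varies continuously under mesh refinement; for a
#' non-monotonic profile the per-cell volume sum is used instead.
#'
#' @param solution A steady `islet_solution`.
#' @param params Parameter set; defaults to the one stored on the solution.
#' @return Viability in percent (unrounded; screening tables round to one
#'   decimal).
#' @export
#' @examples
#' sol <- simulate_scenario(scenario(160, 10, 150, 50), model_params(),
#'                          numerics_config(n_cells = 100))
#' viability_percent(sol)    # 100: small islet, thin shell
viability_percent <- function(solution, params = solution$params) {
  stop_if_not_steady(solution)
  a <- solution$mesh$islet_radius
  rc <- anoxic_core_radius(solution, params)
  if (is.na(rc)) {   # non-monotone profile: fall back to cell-volume sum
    isl <- solution$mesh$region == "islet"
    vol <- solution$mesh$cell_volumes[isl]
    alive <- solution$p_ox[isl] >= params$p_crit
    return(100 * sum(vol[alive]) / sum(vol))
  }
  100 * (1 - (min(rc, a) / a)^3)
}

#' Anoxic core radius
#'
#' Largest radius below which the steady oxygen profile sits under the
#' critical pressure everywhere — the predicted core-necrosis radius.
#' Linear interpolation between cell centers; 0 if the whole islet is
#' above threshold, the islet radius if the whole islet is below. Returns
#' `NA` if the islet profile is non-monotonic (never the case for the
#' physical model, but guarded).
#'
#' @inheritParams viability_percent
#' @return Radius in um.
#' @export
anoxic_core_radius <- function(solution, params = solution$params) {
  stop_if_not_steady(solution)
  isl <- solution$mesh$region == "islet"
  r <- solution$mesh$cell_centers[isl]
  p <- solution$p_ox[isl]
  pc <- params$p_crit
  if (all(p >= pc)) return(0)
  if (all(p < pc)) return(solution$mesh$islet_radius)
  if (any(diff(p) < -1e-9 * max(p))) return(NA_real_)
  i <- max(which(p < pc))
  r[i] + (pc - p[i]) / (p[i + 1] - p[i]) * (r[i + 1] - r[i])
}

#' Normalized insulin secretion percentage
#'
#' Volume integral of the local insulin secretion rate over the islet,
#' relative to the unconstrained maximum `S_max` times the islet volume —
#' i.e. secretion as a percentage of what a fully oxygenated islet at
#' saturating glucose would deliver. This is the normalization that makes a
#' small islet behind a thin shell at high glucose approach 100.
#'
#' @inheritParams viability_percent
#' @return Secretion in percent (unrounded; screening tables round to two
#'   decimals).
#' @export
secretion_percent <- function(solution, params = solution$params) {
  stop_if_not_steady(solution)
  if (params$S_max <= 0) stop("secretion_percent requires S_max > 0")
  isl <- solution$mesh$region == "islet"
  vol <- solution$mesh$cell_volumes[isl]
  rate <- insulin_secretion_rate(solution$p_ox[isl], solution$glucose[isl], params)
  100 * sum(rate * vol) / (params$S_max * sum(vol))
}

stop_if_not_steady <- function(solution) {
  if (!isTRUE(solution$steady_state_reached))
    stop("metric requires a steady solution (steady_state_reached is FALSE)")
}

#' Glucose stimulation index
#'
#' Ratio of insulin secreted under high-glucose stimulation to basal
#' secretion, the standard functional quality measure of beta-cells in a
#' glucose-stimulated insulin secretion (GSIS) assay. Reported rounded to
#' two decimals, matching assay reporting convention.
#'
#' @param basal_secretion Basal insulin secretion (e.g. pmol/l; > 0).
#' @param stimulated_secretion High-glucose insulin secretion (same units).
#' @return Stimulation index (ratio, 2 decimals).
#' @export
#' @examples
#' stimulation_index(16.4, 31.7)   # 1.93
stimulation_index <- function(basal_secretion, stimulated_secretion) {
  if (!is.numeric(basal_secretion) || any(basal_secretion <= 0))
    stop("basal secretion must be > 0")
  if (!is.numeric(stimulated_secretion) || any(stimulated_secretion < 0))
    stop("stimulated secretion must be >= 0")
  round(stimulated_secretion / basal_secretion, 2)
}

#' Reduce a solution to one screening record
#'
#' @param solution A steady `islet_solution`.
#' @return A one-row `data.frame` with the scenario, viability %, insulin
#'   secretion %, anoxic core radius and diagnostics.
#' @export
screen_record <- function(solution) {
  scen <- solution$scenario
  data.frame(p_bath_mmHg = scen$p_bath,
             g_bath_mM = scen$g_bath,
             shell_um = scen$shell_thickness,
             islet_diameter_um = scen$islet_diameter,
             viability_pct = viability_percent(solution),
             secretion_pct = secretion_percent(solution),
             anoxic_core_radius_um = anoxic_core_radius(solution),
             steady = solution$steady_state_reached,
             flux_residual = max(solution$flux_balance_residual),
             error = NA_character_,
             stringsAsFactors = FALSE)
}
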