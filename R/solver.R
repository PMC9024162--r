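#' Define a simulated encapsulation condition
#'
#' One scenario = one capsule design point: inflow (bath) oxygen partial
#' pressure, bath glucose concentration, islet diameter and hydrogel shell
#' thickness. The bath values act as fixed Dirichlet boundary values on the
#' outer capsule surface and as the initial interior values for oxygen and
#' glucose (the capsule is equilibrated with the bath before consumption
#' starts); insulin starts at zero.
#'
#' @param p_bath Inflow oxygen partial pressure, mmHg, in \[0, 760\].
#' @param g_bath Bath glucose concentration, mM (>= 0).
#' @param islet_diameter Islet diameter, um, in (0, 2000\].
#' @param shell_thickness Hydrogel shell thickness, um, in \[0, 5000\].
#' @return An object of class `islet_scenario`.
#' @export
#' @examples
#' scenario(160, 10, 500, 50)
scenario <- function(p_bath, g_bath, islet_diameter, shell_thickness) {
  if (!is.numeric(p_bath) || p_bath < 0 || p_bath > 760)
    stop("p_bath must be in [0, 760] mmHg")
  if (!is.numeric(g_bath) || g_bath < 0)
    stop("g_bath must be >= 0 mM")
  if (!is.numeric(islet_diameter) || islet_diameter <= 0 || islet_diameter > 2000)
    stop("islet_diameter must be in (0, 2000] um")
  if (!is.numeric(shell_thickness) || shell_thickness < 0 || shell_thickness > 5000)
    stop("shell_thickness must be in [0, 5000] um")
  structure(list(p_bath = as.numeric(p_bath), g_bath = as.numeric(g_bath),
                 islet_diameter = as.numeric(islet_diameter),
                 shell_thickness = as.numeric(shell_thickness)),
            class = "islet_scenario")
}

#' @export
print.islet_scenario <- function(x, ...) {
  cat(sprintf("<scenario> pO2 %g mmHg | glucose %g mM | islet %g um | shell %g um\n",
              x$p_bath, x$g_bath, x$islet_diameter, x$shell_thickness))
  invisible(x)
}

#' Numerical configuration for the time integrator
#'
#' The defaults honour the reference numerics of the screening study: a
#' diffusion step size of at most 0.005 s and at least 60 s of simulated
#' time, after which integration continues until the per-second relative
#' field change falls below `ss_tol`. Because backward Euler is
#' unconditionally stable and its steady state does not depend on the step
#' size, the step may grow geometrically once the mandatory window has
#' passed (`dt_ramp`/`dt_max`); this accelerates convergence for thick
#' shells whose diffusive time scales far exceed 60 s without changing the
#' converged fields.
#'
#' @param dt Time step, s (default 0.005; must be positive).
#' @param t_end Minimum simulated time, s (default 60; enforced >= 60 when
#'   `strict_numerics = TRUE`).
#' @param n_cells Mesh cells (default 400).
#' @param ss_tol Steady-state criterion: maximum relative field change per
#'   simulated second (default 1e-8, tight enough that the flux-balance
#'   residual stays well below 1% even for the slow insulin transients of
#'   millimetre-thick shells).
#' @param scheme `"implicit"` (backward Euler, default) or `"explicit"`
#'   (forward Euler; conditionally stable, for cross-checks on coarse
#'   meshes).
#' @param t_max Hard wall on simulated time, s; non-convergence by `t_max`
#'   is flagged on the solution, never silent.
#' @param dt_ramp Geometric step-growth factor applied after `t_end`
#'   (1 disables ramping; ignored for the explicit scheme).
#' @param dt_max Cap on the ramped step, s.
#' @param refinement Mesh refinement policy, see [build_radial_mesh()].
#' @param ins_boundary `"sink"` (Dirichlet 0: the host circulation removes
#'   hormone, default) or `"reflect"` (zero-flux) for insulin at the outer
#'   boundary.
#' @param strict_numerics Keep the `t_end >= 60` s and `dt <= 0.005` s
#'   guarantees (default TRUE).
#' @return An object of class `islet_numerics`.
#' @export
numerics_config <- function(dt = 0.005, t_end = 60, n_cells = 400,
                            ss_tol = 1e-8,
                            scheme = c("implicit", "explicit"),
                            t_max = 2e5, dt_ramp = 1.05, dt_max = 2,
                            refinement = "uniform",
                            ins_boundary = c("sink", "reflect"),
                            strict_numerics = TRUE) {
  scheme <- match.arg(scheme)
  ins_boundary <- match.arg(ins_boundary)
  if (dt <= 0) stop("dt must be > 0")
  if (ss_tol <= 0) stop("ss_tol must be > 0")
  if (strict_numerics && t_end < 60)
    stop("t_end must be >= 60 s in strict numerics mode")
  if (strict_numerics && dt > 0.005 && scheme == "implicit")
    stop("dt must be <= 0.005 s in strict numerics mode")
  if (t_max < t_end) stop("t_max must be >= t_end")
  structure(list(dt = dt, t_end = t_end, n_cells = as.integer(n_cells),
                 ss_tol = ss_tol, scheme = scheme, t_max = t_max,
                 dt_ramp = if (scheme == "explicit") 1 else dt_ramp,
                 dt_max = dt_max, refinement = refinement,
                 ins_boundary = ins_boundary,
                 strict_numerics = strict_numerics),
            class = "islet_numerics")
}

#' Simulate one scenario to steady state
#'
#' Integrates the coupled radial system
#' \deqn{\partial_t u = \frac{1}{r^2}\partial_r\!\left(r^2 D(r)\,\partial_r u\right) + s(u,\dots)}
#' for oxygen partial pressure, glucose and insulin on the islet + shell
#' mesh. Consumption sinks (oxygen, glucose) and the secretion source
#' (insulin) act in islet cells only; the gel is inert apart from optional
#' first-order insulin degradation. Outer boundary: Dirichlet at the bath
#' values (insulin: perfect sink by default); centre: zero flux by symmetry.
#'
#' @param scen An `islet_scenario` (or a list coercible to one).
#' @param params An `islet_params`.
#' @param numerics An `islet_numerics`.
#' @param store_times Optional numeric vector of simulated times at which
#'   field snapshots are kept on the solution.
#' @return An object of class `islet_solution`: the mesh, final fields
#'   `p_ox` (mmHg), `glucose` (mM), `insulin` (a.u.), convergence
#'   diagnostics (`steady_state_reached`, `t_final`, `steps`,
#'   `rate_change`), per-species `flux_balance_residual` (filled by
#'   [check_flux_balance()]), and the scenario/params/numerics provenance.
#' @export
#' @examples
#' sol <- simulate_scenario(scenario(160, 10, 150, 50), model_params(),
#'                          numerics_config(n_cells = 100))
#' sol$steady_state_reached
#' range(sol$p_ox)
simulate_scenario <- function(scen, params = model_params(),
                              numerics = numerics_config(),
                              store_times = numeric(0)) {
  if (!inherits(scen, "islet_scenario"))
    scen <- do.call(scenario, as.list(scen))
  validate_params(params)
  if (!inherits(numerics, "islet_numerics"))
    stop("numerics must be created with numerics_config()")
  mesh <- build_radial_mesh(scen$islet_diameter, scen$shell_thickness,
                            numerics$n_cells, numerics$refinement)
  isl <- mesh$region == "islet"
  Dcell <- cbind(ifelse(isl, params$D_ox_islet, params$D_ox_gel),
                 ifelse(isl, params$D_glc_islet, params$D_glc_gel),
                 ifelse(isl, params$D_ins_islet, params$D_ins_gel))
  res <- .solve_rd_cpp(mesh$face_positions, mesh$cell_centers,
                       mesh$cell_volumes, as.integer(isl), Dcell,
                       c(scen$p_bath, scen$g_bath, 0),
                       as.integer(numerics$ins_boundary == "sink"),
                       unclass(params),
                       numerics$dt, numerics$t_end, numerics$t_max,
                       numerics$ss_tol, numerics$dt_ramp, numerics$dt_max,
                       as.integer(numerics$scheme == "explicit"),
                       as.numeric(store_times))
  sol <- structure(list(mesh = mesh,
                        p_ox = res$p_ox, glucose = res$glucose,
                        insulin = res$insulin,
                        steady_state_reached = res$steady,
                        t_final = res$t_final, steps = res$steps,
                        rate_change = res$rate_change,
                        snapshots = res$snapshots,
                        snapshot_times = res$snapshot_times,
                        flux_balance_residual = NULL,
                        scenario = scen, params = params,
                        numerics = numerics),
                   class = "islet_solution")
  if (!res$steady)
    warning(sprintf(paste0("steady state not reached within t_max = %g s ",
                           "(max relative change/s: %.3g); solution flagged"),
                    numerics$t_max, max(res$rate_change)))
  sol$flux_balance_residual <- check_flux_balance(sol, require_steady = FALSE)
  sol
}

#' @export
print.islet_solution <- function(x, ...) {
  cat(sprintf("<islet_solution> %s", format(x$scenario)))
  print(x$scenario)
  cat(sprintf("  steady: %s (t = %.1f s, %d steps)\n",
              x$steady_state_reached, x$t_final, as.integer(x$steps)))
  cat(sprintf("  centre pO2 %.3f mmHg | centre glucose %.3f mM\n",
              x$p_ox[1], x$glucose[1]))
  invisible(x)
}

#' Steady-state flux balance check
#'
#' At steady state the diffusive flux through the outer boundary must equal
#' the volume-integrated reaction term: consumption for oxygen and glucose,
#' secretion minus gel degradation for insulin. Returns the per-species
#' relative residual; a residual well below 1 is a self-consistency check
#' on the discretization and the convergence criterion. The degenerate
#' no-reaction case (0/0) is reported as 0.
#'
#' @param solution An `islet_solution`.
#' @param require_steady Reject non-steady solutions (default TRUE).
#' @return Named numeric vector `c(oxygen=, glucose=, insulin=)`.
#' @export
check_flux_balance <- function(solution, require_steady = TRUE) {
  if (require_steady && !isTRUE(solution$steady_state_reached))
    stop("flux balance requires a steady solution")
  mesh <- solution$mesh
  par <- solution$params
  scen <- solution$scenario
  isl <- mesh$region == "islet"
  n <- mesh$n_cells
  b <- mesh$outer_radius
  Ab <- 4 * pi * b^2
  dxb <- b - mesh$cell_centers[n]
  vol <- mesh$cell_volumes

  res <- c(oxygen = 0, glucose = 0, insulin = 0)
  # boundary-cell diffusivities follow its region (the outer cell is islet
  # tissue when the shell thickness is zero)
  outer_gel <- mesh$region[n] == "gel"
  D_ox_b <- if (outer_gel) par$D_ox_gel else par$D_ox_islet
  D_glc_b <- if (outer_gel) par$D_glc_gel else par$D_glc_islet
  D_ins_b <- if (outer_gel) par$D_ins_gel else par$D_ins_islet

  # oxygen: inward flux (as dissolved mass) vs integrated consumption
  flux_in <- Ab * D_ox_b * (scen$p_bath - solution$p_ox[n]) / dxb * par$alpha_ox
  cons <- sum(oxygen_consumption_rate(solution$p_ox[isl], solution$glucose[isl], par) * vol[isl])
  scale <- Ab * D_ox_b * max(scen$p_bath, 1) / b * par$alpha_ox
  res["oxygen"] <- rel_residual(flux_in, cons, scale)

  flux_in <- Ab * D_glc_b * (scen$g_bath - solution$glucose[n]) / dxb
  cons <- sum(glucose_consumption_rate(solution$p_ox[isl], solution$glucose[isl], par) * vol[isl])
  scale <- Ab * D_glc_b * max(scen$g_bath, 1) / b
  res["glucose"] <- rel_residual(flux_in, cons, scale)

  # insulin: outward flux vs integrated secretion minus gel degradation
  if (solution$numerics$ins_boundary == "sink") {
    flux_out <- Ab * D_ins_b * (solution$insulin[n] - 0) / dxb
  } else flux_out <- 0
  sec <- sum(insulin_secretion_rate(solution$p_ox[isl], solution$glucose[isl], par) * vol[isl])
  deg <- par$k_deg_gel * sum(solution$insulin[!isl] * vol[!isl])
  res["insulin"] <- rel_residual(flux_out, sec - deg, par$S_max * sum(vol[isl]))
  res
}

# Relative flux/reaction mismatch. `scale` is a characteristic transport
# magnitude for the species; when both terms are negligible against it
# (e.g. pure diffusion: 0/0) the residual is defined as 0.
rel_residual <- function(flux, reaction, scale) {
  if (max(abs(flux), abs(reaction)) < 1e-8 * scale) return(0)
  abs(flux - reaction) / max(abs(reaction), 1e-300)
}

#' Dump a solution as CSV plus a JSON sidecar
#'
#' CSV columns: `cell_index`, `r_um`, `region`, `pO2_mmHg`, `glucose_mM`,
#' `insulin_au`. The sidecar `<path>.json` records scenario, parameter
#' hash, numerics and convergence diagnostics.
#'
#' @param solution An `islet_solution`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_solution <- function(solution, path) {
  mesh <- solution$mesh
  df <- data.frame(cell_index = seq_len(mesh$n_cells),
                   r_um = mesh$cell_centers,
                   region = as.character(mesh$region),
                   pO2_mmHg = solution$p_ox,
                   glucose_mM = solution$glucose,
                   insulin_au = solution$insulin)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(scenario = unclass(solution$scenario),
               params_hash = params_hash(solution$params),
               numerics = unclass(solution$numerics),
               diagnostics = list(
                 steady_state_reached = solution$steady_state_reached,
                 t_final = solution$t_final,
                 steps = solution$steps,
                 flux_balance_residual = as.list(solution$flux_balance_residual)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# Deterministic short hash of a parameter set (provenance tagging).
# Polynomial rolling hash modulo a Mersenne prime; plain doubles only, so
# it stays exact (< 2^53) and portable.
params_hash <- function(p) {
  s <- paste(names(p), vapply(p, function(v) sprintf("%.15g", v), ""),
             sep = "=", collapse = ";")
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% m
  sprintf("%08x", h)
}
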