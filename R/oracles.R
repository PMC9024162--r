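#' Analytic oracle cases for the steady radial problem
#'
#' A zeroth-order (constant) volumetric consumption rate inside a sphere of
#' radius `a`, zero reaction in a concentric shell out to `b`, and a fixed
#' boundary value at `b` admit a closed-form steady profile. These cases
#' exercise the solver's continuum limit independently of its
#' discretization: the oracle never calls the solver.
#'
#' @param a Islet radius, um.
#' @param b Outer radius, um (>= a).
#' @param R Constant volumetric consumption rate in field-units/s (e.g.
#'   mmHg/s for an oxygen-like field); 0 gives pure diffusion.
#' @param D_in,D_out Diffusivity inside / outside the sphere, um^2/s.
#' @param c_bath Boundary value at r = b (field units).
#' @param description Free-text label.
#' @param tol Relative tolerance attached to the case (> 0).
#' @return An object of class `oracle_case`.
#' @export
#' @examples
#' oc <- oracle_case(a = 75, b = 125, R = 2, D_in = 2000, D_out = 3000,
#'                   c_bath = 90)
#' analytic_sphere_profile(oc, c(0, 75, 125))
oracle_case <- function(a, b, R, D_in, D_out, c_bath,
                        description = "zeroth-order sphere + shell",
                        tol = 5e-3) {
  stopifnot(a > 0, b >= a, D_in > 0, D_out > 0, R >= 0, tol > 0)
  structure(list(a = a, b = b, R = R, D_in = D_in, D_out = D_out,
                 c_bath = c_bath, description = description, tol = tol),
            class = "oracle_case")
}

#' Closed-form steady profile of an oracle case
#'
#' Inside the sphere: `c(r) = c(a) - (R / 6 D_in) (a^2 - r^2)`; in the
#' shell: `c(r) = c_bath - (Q / 4 pi D_out)(1/r - 1/b)` with
#' `Q = (4/3) pi a^3 R` the total consumption, continuous at r = a.
#' Negative values are not clipped: a profile dipping below zero signals
#' that the zeroth-order assumption is incompatible with the inputs (the
#' regime the survival cutoff exists for).
#'
#' @param case An `oracle_case`.
#' @param r Radii, um, within \[0, b\].
#' @return Field values at `r`.
#' @export
analytic_sphere_profile <- function(case, r) {
  if (any(r < 0 | r > case$b)) stop("r must lie within [0, b]")
  Q <- (4 / 3) * pi * case$a^3 * case$R
  c_a <- case$c_bath - Q / (4 * pi * case$D_out) * (1 / case$a - 1 / case$b)
  ifelse(r <= case$a,
         c_a - case$R / (6 * case$D_in) * (case$a^2 - r^2),
         case$c_bath - Q / (4 * pi * case$D_out) * (1 / r - 1 / case$b))
}

#' Independent shooting solution of the steady radial two-point problem
#'
#' Integrates the steady ODE `(1/r^2) d/dr (r^2 D(r) dc/dr) = R * 1{r < a}`
#' outward from the centre with a stiff ODE integrator (lsoda), shooting on
#' the centre value until the boundary condition `c(b) = c_bath` is met.
#' Used as a second, discretization-free route to the oracle profiles; it
#' shares no code with the finite-volume solver.
#'
#' @param case An `oracle_case`.
#' @param r Radii at which to evaluate the solution.
#' @return Field values at `r`.
#' @export
shooting_sphere_profile <- function(case, r) {
  if (any(r < 0 | r > case$b)) stop("r must lie within [0, b]")
  a <- case$a; b <- case$b
  Dfun <- function(x) if (x < a) case$D_in else case$D_out
  eps <- 1e-6 * b
  rhs <- function(x, y, parms) {
    # y1 = c, y2 = r^2 D c'
    src <- if (x < a) case$R else 0
    list(c(y[2] / (x^2 * Dfun(x)), src * x^2))
  }
  bval <- function(c0) {
    out <- deSolve::lsoda(c(c0, 0), times = c(eps, b), func = rhs,
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    out[nrow(out), 2] - case$c_bath
  }
  # centre value bracket: pure-diffusion value down to a generous deficit
  drop_guess <- case$R * a^2 / (6 * case$D_in) +
    case$R * a^3 * (1 / a - 1 / b) / (3 * case$D_out)
  lo <- case$c_bath - 10 * drop_guess - 1
  c0 <- stats::uniroot(bval, c(lo, case$c_bath + 1), tol = 1e-10)$root
  out <- deSolve::lsoda(c(c0, 0), times = unique(c(eps, sort(pmax(r, eps)))),
                        func = rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
  stats::approx(out[, 1], out[, 2], xout = pmax(r, eps))$y
}

#' Seeded random scenario grids
#'
#' Draws `n` scenarios by Latin-hypercube sampling within the given ranges
#' (defaults: the screening study's stated spans of oxygen, glucose, islet
#' size and shell thickness). Fully reproducible for a given seed; every
#' draw satisfies the scenario invariants.
#'
#' @param seed Integer seed.
#' @param n Number of scenarios (>= 0).
#' @param ranges Named list of `c(min, max)` for `p_bath` (mmHg),
#'   `g_bath` (mM), `islet_diameter` (um), `shell_thickness` (um).
#' @return A data.frame of scenarios.
#' @export
#' @examples
#' generate_scenario_grid(1, 3)
generate_scenario_grid <- function(seed, n,
                                   ranges = list(p_bath = c(90, 270),
                                                 g_bath = c(5, 25),
                                                 islet_diameter = c(100, 500),
                                                 shell_thickness = c(0, 1000))) {
  need <- c("p_bath", "g_bath", "islet_diameter", "shell_thickness")
  if (!setequal(names(ranges), need))
    stop("ranges must name exactly: ", paste(need, collapse = ", "))
  lims <- list(p_bath = c(0, 760), g_bath = c(0, Inf),
               islet_diameter = c(1e-9, 2000), shell_thickness = c(0, 5000))
  for (f in need) {
    rg <- ranges[[f]]
    if (length(rg) != 2 || rg[1] > rg[2] || rg[1] < lims[[f]][1] || rg[2] > lims[[f]][2])
      stop("range for '", f, "' violates scenario invariants")
  }
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0")
  if (n == 0)
    return(data.frame(p_bath = numeric(0), g_bath = numeric(0),
                      islet_diameter = numeric(0), shell_thickness = numeric(0)))
  set.seed(seed)
  u <- lhs::randomLHS(n, 4)
  df <- data.frame(
    p_bath = ranges$p_bath[1] + u[, 1] * diff(ranges$p_bath),
    g_bath = ranges$g_bath[1] + u[, 2] * diff(ranges$g_bath),
    islet_diameter = ranges$islet_diameter[1] + u[, 3] * diff(ranges$islet_diameter),
    shell_thickness = ranges$shell_thickness[1] + u[, 4] * diff(ranges$shell_thickness))
  df
}

#' Multiplicative log-normal perturbation of kinetic constants
#'
#' Robustness harness: perturbs the kinetic constants (`R_ox_max`,
#' `K_m_ox`, `phi_glc_amp`, `R_glc_max`, `K_m_glc`, `S_max`, `K_s`) by
#' independent log-normal factors with relative standard deviation
#' `relative_sd`, resampling (up to 100 times) any draw that violates the
#' parameter invariants. Diffusivities, thresholds and exponents are left
#' untouched.
#'
#' @param params An `islet_params`.
#' @param seed Integer seed.
#' @param relative_sd Relative standard deviation in \[0, 0.5\].
#' @return A valid perturbed `islet_params`.
#' @export
perturb_params <- function(params, seed, relative_sd) {
  validate_params(params)
  if (!is.numeric(relative_sd) || relative_sd < 0 || relative_sd > 0.5)
    stop("relative_sd must be in [0, 0.5]")
  if (relative_sd == 0) return(params)
  kin <- c("R_ox_max", "K_m_ox", "phi_glc_amp", "R_glc_max", "K_m_glc",
           "S_max", "K_s")
  set.seed(seed)
  sdlog <- sqrt(log(1 + relative_sd^2))
  for (trial in 1:100) {
    p <- params
    fac <- stats::rlnorm(length(kin), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    for (i in seq_along(kin)) p[[kin[i]]] <- params[[kin[i]]] * fac[i]
    ok <- tryCatch({ validate_params(p); TRUE }, error = function(e) FALSE)
    if (ok) return(p)
  }
  stop("could not draw an invariant-preserving perturbation")
}
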