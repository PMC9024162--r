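#' Model parameters for encapsulated-islet transport
#'
#' Bundles every physical constant of the coupled oxygen / glucose / insulin
#' reaction-diffusion model: region-wise diffusivities, oxygen solubility,
#' Michaelis-Menten consumption kinetics, the Hill law for glucose-stimulated
#' insulin secretion, the glucose modulation of oxygen demand, and the two
#' oxygen thresholds (secretion shut-down and the critical survival pressure).
#'
#' Units follow common practice for islet transport models: lengths in
#' micrometres, time in seconds, oxygen as partial pressure in mmHg,
#' glucose in mM (= mol/m3), volumetric rates in mol m-3 s-1, insulin in
#' arbitrary units. Oxygen partial pressure converts to dissolved
#' concentration through the solubility `alpha_ox` (mM/mmHg).
#'
#' @param D_ox_gel,D_ox_islet Oxygen diffusivity in hydrogel / islet tissue
#'   (um^2/s). Islet diffusivity must not exceed the gel value (transport
#'   through packed tissue is hindered relative to hydrogel).
#' @param D_glc_gel,D_glc_islet Glucose diffusivity (um^2/s); the gel value
#'   must be more than four-fold below the gel oxygen diffusivity, which it
#'   is for any aqueous hydrogel.
#' @param D_ins_gel,D_ins_islet Insulin diffusivity (um^2/s).
#' @param alpha_ox Oxygen solubility (mM per mmHg), Henry's law.
#' @param R_ox_max Maximal volumetric oxygen consumption rate of islet
#'   tissue at basal glucose (mol m-3 s-1).
#' @param K_m_ox Michaelis constant of oxygen consumption (mmHg).
#' @param phi_glc_amp,K_phi,n_phi Amplitude (dimensionless), half-point (mM)
#'   and Hill exponent of the glucose modulation of oxygen consumption:
#'   hyperglycemia raises secretory work and with it oxygen demand, so the
#'   consumption maximum is scaled by `1 + phi_glc_amp * Hill(g)`.
#' @param R_glc_max Maximal volumetric glucose consumption (mol m-3 s-1).
#' @param K_m_glc Michaelis constant of glucose consumption (mM).
#' @param S_max Maximal volumetric insulin secretion rate (a.u. m-3 s-1).
#' @param K_s,n_s Half-point (mM) and Hill exponent of glucose-stimulated
#'   insulin secretion.
#' @param p_sec_th Oxygen partial pressure (mmHg) at the centre of the
#'   secretion shut-down ramp. Must exceed `p_crit`: secretory function is
#'   lost before the cells die.
#' @param sec_width Full width (mmHg) of the smoothstep secretion ramp; the
#'   gate is exactly 0 below `p_sec_th - sec_width/2` and exactly 1 above
#'   `p_sec_th + sec_width/2`.
#' @param p_crit Critical oxygen partial pressure for cell survival (mmHg);
#'   default 0.07 mmHg.
#' @param delta_smooth Width (mmHg) of the smooth survival ramp replacing
#'   the hard viability step in the rate laws.
#' @param k_deg_gel First-order insulin degradation rate in the gel (1/s);
#'   0 by default (hormone loss in the capsule material switched off).
#'
#' @details
#' The shipped defaults combine literature transport constants for islet
#' tissue and aqueous hydrogels with a kinetic calibration: `R_ox_max`,
#' `phi_glc_amp`, `K_m_ox`, `D_ox_islet`, `K_s`, `n_s`, `p_sec_th` and
#' `sec_width` were fitted once against the thin-shell rows of the
#' reference screening table bundled with the package (see
#' [table1_reference()]) and are frozen. See the methods vignette for the
#' calibration protocol.
#'
#' @return An object of class `islet_params` (a validated named list).
#' @seealso [read_params()], [write_params()], [oxygen_consumption_rate()],
#'   [insulin_secretion_rate()], [survival_weight()]
#' @export
#' @examples
#' p <- model_params()
#' p$p_crit
model_params <- function(D_ox_gel = 3000,
                         D_ox_islet = .islet_defaults$D_ox_islet,
                         D_glc_gel = 600,
                         D_glc_islet = 300,
                         D_ins_gel = 150,
                         D_ins_islet = 100,
                         alpha_ox = 1.27e-3,
                         R_ox_max = .islet_defaults$R_ox_max,
                         K_m_ox = .islet_defaults$K_m_ox,
                         phi_glc_amp = .islet_defaults$phi_glc_amp,
                         K_phi = .islet_defaults$K_s,
                         n_phi = .islet_defaults$n_s,
                         R_glc_max = 5.7e-3,
                         K_m_glc = 10,
                         S_max = 1,
                         K_s = .islet_defaults$K_s,
                         n_s = .islet_defaults$n_s,
                         p_sec_th = .islet_defaults$p_sec_th,
                         sec_width = .islet_defaults$sec_width,
                         p_crit = 0.07,
                         delta_smooth = 0.01,
                         k_deg_gel = 0) {
  p <- list(D_ox_gel = D_ox_gel, D_ox_islet = D_ox_islet,
            D_glc_gel = D_glc_gel, D_glc_islet = D_glc_islet,
            D_ins_gel = D_ins_gel, D_ins_islet = D_ins_islet,
            alpha_ox = alpha_ox,
            R_ox_max = R_ox_max, K_m_ox = K_m_ox,
            phi_glc_amp = phi_glc_amp, K_phi = K_phi, n_phi = n_phi,
            R_glc_max = R_glc_max, K_m_glc = K_m_glc,
            S_max = S_max, K_s = K_s, n_s = n_s,
            p_sec_th = p_sec_th, sec_width = sec_width,
            p_crit = p_crit, delta_smooth = delta_smooth,
            k_deg_gel = k_deg_gel)
  p <- lapply(p, function(x) { stopifnot(is.numeric(x), length(x) == 1); as.numeric(x) })
  class(p) <- "islet_params"
  validate_params(p)
  p
}

# Calibrated kinetic constants (frozen; see methods vignette for protocol).
.islet_defaults <- list(
  D_ox_islet  = 2000,
  R_ox_max    = 3.56936e-2,
  K_m_ox      = 1.092402,
  phi_glc_amp = 1.102055,
  K_s         = 7.133535,
  n_s         = 2.543032,
  p_sec_th    = 18.57523,
  sec_width   = 36.7504
)

#' @rdname model_params
#' @export
default_params <- function() model_params()

#' Validate an `islet_params` object
#'
#' Checks positivity, the islet-vs-gel diffusivity ordering, the glucose/
#' oxygen diffusivity contrast, and the ordering of the two oxygen
#' thresholds. Called by every constructor and parser; exported so perturbed
#' or hand-edited sets can be re-checked.
#'
#' @param p An `islet_params` object (or bare named list with the same fields).
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(p) {
  need <- names(formals(model_params))
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter field(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(p), need)
  if (length(extra)) stop("unknown parameter field(s): ", paste(extra, collapse = ", "))
  for (f in need) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number")
  }
  diff_pos <- c("D_ox_gel", "D_ox_islet", "D_glc_gel", "D_glc_islet",
                "D_ins_gel", "D_ins_islet")
  for (f in diff_pos) if (p[[f]] <= 0) stop("diffusivity '", f, "' must be > 0")
  if (p$D_ox_islet > p$D_ox_gel) stop("D_ox_islet must not exceed D_ox_gel")
  if (p$D_glc_islet > p$D_glc_gel) stop("D_glc_islet must not exceed D_glc_gel")
  if (p$D_ins_islet > p$D_ins_gel) stop("D_ins_islet must not exceed D_ins_gel")
  if (p$D_glc_gel >= p$D_ox_gel / 4)
    stop("D_glc_gel must be more than four-fold below D_ox_gel")
  for (f in c("alpha_ox", "K_m_ox", "K_m_glc", "K_s", "K_phi", "p_crit",
              "delta_smooth", "sec_width"))
    if (p[[f]] <= 0) stop("parameter '", f, "' must be > 0")
  for (f in c("R_ox_max", "R_glc_max", "S_max", "phi_glc_amp", "k_deg_gel"))
    if (p[[f]] < 0) stop("parameter '", f, "' must be >= 0")
  if (p$n_s < 1 || p$n_phi < 1) stop("Hill exponents must be >= 1")
  if (p$p_sec_th <= p$p_crit)
    stop("p_sec_th must exceed p_crit (secretion fails before death)")
  invisible(p)
}

#' @export
print.islet_params <- function(x, ...) {
  cat("<islet_params>\n")
  for (f in names(x)) cat(sprintf("  %-12s %g\n", f, x[[f]]))
  invisible(x)
}

#' Read / write a parameter file
#'
#' Flat YAML or JSON with exactly the `islet_params` field names; unknown
#' keys are rejected, missing keys are an error. `write_params()` followed
#' by `read_params()` reproduces the parameter set exactly.
#'
#' @param path File path; format chosen from the extension (`.yaml`/`.yml`
#'   or `.json`) unless `format` is given.
#' @param format `"yaml"` or `"json"`.
#' @return `read_params()` returns an `islet_params`; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  raw <- if (format == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  p <- lapply(raw, as.numeric)
  class(p) <- "islet_params"
  validate_params(p)
  p
}

#' @rdname read_params
#' @param p An `islet_params` object.
#' @export
write_params <- function(p, path, format = c("auto", "yaml", "json")) {
  validate_params(p)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  x <- unclass(p)
  if (format == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

hill_fn <- function(x, K, n) {
  ifelse(x <= 0, 0, x^n / (x^n + K^n))
}

#' Survival weight of islet cells at a local oxygen partial pressure
#'
#' Smooth stand-in for the hard viability criterion "cells survive where the
#' local pO2 is at least the critical pressure" (default 0.07 mmHg). A
#' logistic ramp of width `delta_smooth` centred on `p_crit` returns ~0 well
#' below the threshold, 0.5 at the threshold, and ~1 well above; as
#' `delta_smooth -> 0` it converges to the step function. The weight gates
#' all metabolic rate laws so that anoxic (dead) tissue consumes nothing.
#'
#' @param p_ox Oxygen partial pressure, mmHg (vectorized; must be >= 0).
#' @param params An `islet_params` object.
#' @return Fraction in \[0, 1\], same length as `p_ox`.
#' @export
#' @examples
#' survival_weight(c(0, 0.07, 7), model_params())
survival_weight <- function(p_ox, params = model_params()) {
  if (any(p_ox < 0)) stop("p_ox must be >= 0")
  stats::plogis((p_ox - params$p_crit) / (params$delta_smooth / 8))
}

#' Secretion oxygen gate
#'
#' Insulin secretion is an energy-intensive process that fails at oxygen
#' tensions far above the survival limit. The gate is a cubic smoothstep:
#' exactly 0 below `p_sec_th - sec_width/2`, exactly 1 above
#' `p_sec_th + sec_width/2`, C1-smooth in between. Reaching exactly 1 above
#' the ramp makes secretion insensitive to the bath pO2 once the whole islet
#' is comfortably oxygenated.
#'
#' @inheritParams survival_weight
#' @return Fraction in \[0, 1\].
#' @export
sec_gate <- function(p_ox, params = model_params()) {
  if (any(p_ox < 0)) stop("p_ox must be >= 0")
  lo <- params$p_sec_th - params$sec_width / 2
  u <- pmin(1, pmax(0, (p_ox - lo) / params$sec_width))
  u * u * (3 - 2 * u)
}

#' Local volumetric oxygen consumption rate
#'
#' Michaelis-Menten in oxygen, multiplied by a glucose-dependent demand
#' factor `1 + phi_glc_amp * Hill(g; K_phi, n_phi)` (hyperglycemia raises
#' secretory work and hence oxygen consumption) and by the survival weight
#' (dead tissue consumes nothing). Applies to islet tissue only; the caller
#' enforces a zero rate in the cell-free gel.
#'
#' @param p_ox Oxygen partial pressure, mmHg (>= 0, vectorized).
#' @param g Glucose concentration, mM (>= 0, vectorized).
#' @param params An `islet_params` object.
#' @return Rate in mol m-3 s-1.
#' @export
#' @examples
#' p <- model_params()
#' oxygen_consumption_rate(90, 5, p) < oxygen_consumption_rate(90, 25, p)
oxygen_consumption_rate <- function(p_ox, g, params = model_params()) {
  if (any(p_ox < 0) || any(g < 0)) stop("p_ox and g must be >= 0")
  params$R_ox_max * p_ox / (p_ox + params$K_m_ox) *
    (1 + params$phi_glc_amp * hill_fn(g, params$K_phi, params$n_phi)) *
    survival_weight(p_ox, params)
}

#' Local volumetric glucose consumption rate
#'
#' Michaelis-Menten in glucose, gated by the survival weight.
#'
#' @inheritParams oxygen_consumption_rate
#' @return Rate in mol m-3 s-1.
#' @export
glucose_consumption_rate <- function(p_ox, g, params = model_params()) {
  if (any(p_ox < 0) || any(g < 0)) stop("p_ox and g must be >= 0")
  params$R_glc_max * g / (g + params$K_m_glc) * survival_weight(p_ox, params)
}

#' Local volumetric insulin secretion rate
#'
#' Hill law in glucose (half-point `K_s`, exponent `n_s`) scaled by `S_max`
#' and multiplied by the secretion oxygen gate, which shuts secretion down
#' at oxygen tensions well above the survival threshold.
#'
#' @inheritParams oxygen_consumption_rate
#' @return Rate in a.u. m-3 s-1.
#' @export
#' @examples
#' p <- model_params()
#' insulin_secretion_rate(90, c(5, 10, 25), p)  # increasing in glucose
insulin_secretion_rate <- function(p_ox, g, params = model_params()) {
  if (any(p_ox < 0) || any(g < 0)) stop("p_ox and g must be >= 0")
  params$S_max * hill_fn(g, params$K_s, params$n_s) * sec_gate(p_ox, params)
}
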