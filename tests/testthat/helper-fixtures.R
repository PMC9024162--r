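# Shared fixtures: coarse numerics for fast unit tests, and a lazy cache so
# expensive steady-state solutions are computed once per test run.

coarse_num <- function(...) numerics_config(n_cells = 100, ...)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Parameters that turn the model into a zeroth-order oxygen consumer:
# near-zero Michaelis constant, no glucose modulation, no other reactions.
# `rate` is the constant volumetric consumption expressed in mmHg/s.
zeroth_order_params <- function(rate, D_islet = 2000, D_gel = 3000,
                                alpha = 1.27e-3) {
  model_params(D_ox_islet = D_islet, D_ox_gel = D_gel, alpha_ox = alpha,
               R_ox_max = rate * alpha, K_m_ox = 1e-7, phi_glc_amp = 0,
               D_glc_gel = D_gel / 8, D_glc_islet = D_gel / 16,
               R_glc_max = 0, S_max = 1e-9)
}
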