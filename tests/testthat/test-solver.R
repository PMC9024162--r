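test_that("pure diffusion relaxes to the boundary values", {
  par <- model_params(R_ox_max = 0, R_glc_max = 0, S_max = 1e-12)
  sol <- simulate_scenario(scenario(120, 8, 200, 100), par, coarse_num())
  expect_true(sol$steady_state_reached)
  expect_equal(sol$p_ox, rep(120, length(sol$p_ox)), tolerance = 1e-6)
  expect_equal(sol$glucose, rep(8, length(sol$glucose)), tolerance = 1e-6)
  expect_equal(max(abs(sol$insulin)), 0, tolerance = 1e-9)
  expect_equal(unname(check_flux_balance(sol)), c(0, 0, 0), tolerance = 1e-4)
})

test_that("steady state matches the zeroth-order sphere solution without a shell", {
  R <- 0.6  # mmHg/s; centre stays far above p_crit
  par <- zeroth_order_params(R, D_islet = 2000, D_gel = 2000)
  sol <- cached("zo_noshell",
                simulate_scenario(scenario(90, 10, 500, 0), par,
                                  numerics_config(n_cells = 200)))
  oc <- oracle_case(a = 250, b = 250, R = R, D_in = 2000, D_out = 2000,
                    c_bath = 90)
  ref <- analytic_sphere_profile(oc, sol$mesh$cell_centers)
  expect_true(sol$steady_state_reached)
  expect_lt(max(abs(sol$p_ox - ref) / ref), 5e-3)
  # closed-form centre value: c_bath - R a^2 / 6 D
  expect_equal(sol$p_ox[1], 90 - R * 250^2 / (6 * 2000), tolerance = 1e-3)
})

test_that("steady state matches the sphere+shell solution across the interface", {
  R <- 0.5
  par <- zeroth_order_params(R, D_islet = 1500, D_gel = 3000)
  sol <- cached("zo_shell",
                simulate_scenario(scenario(90, 10, 300, 150), par,
                                  numerics_config(n_cells = 200)))
  oc <- oracle_case(a = 150, b = 300, R = R, D_in = 1500, D_out = 3000,
                    c_bath = 90)
  ref <- analytic_sphere_profile(oc, sol$mesh$cell_centers)
  expect_lt(max(abs(sol$p_ox - ref) / ref), 5e-3)
  # pressure drop across the gel equals Q (1/a - 1/b) / (4 pi D_gel)
  Q <- 4 / 3 * pi * 150^3 * R
  drop_shell <- Q * (1 / 150 - 1 / 300) / (4 * pi * 3000)
  ia <- max(which(sol$mesh$region == "islet"))
  expect_equal(90 - analytic_sphere_profile(oc, 150), drop_shell,
               tolerance = 1e-12)
  expect_equal(sol$p_ox[ia + 1] - 0, ref[ia + 1], tolerance = 1e-2)
})

test_that("flux balance closes for reactive steady states", {
  R <- 0.5
  par <- zeroth_order_params(R, D_islet = 1500, D_gel = 3000)
  sol <- cached("zo_shell",
                simulate_scenario(scenario(90, 10, 300, 150), par,
                                  numerics_config(n_cells = 200)))
  expect_lt(check_flux_balance(sol)[["oxygen"]], 1e-3)
  sol2 <- cached("table1_default_coarse",
                 simulate_scenario(scenario(160, 10, 500, 50),
                                   numerics = coarse_num()))
  expect_true(all(check_flux_balance(sol2) < 1e-2))
  # rejected on a non-steady solution
  nn <- numerics_config(t_max = 60, ss_tol = 1e-14)
  sol3 <- suppressWarnings(
    simulate_scenario(scenario(160, 10, 500, 50), numerics = nn))
  expect_false(sol3$steady_state_reached)
  expect_error(check_flux_balance(sol3), "steady")
})

test_that("fields respect the discrete maximum principle", {
  sol <- cached("table1_default_coarse",
                simulate_scenario(scenario(160, 10, 500, 50),
                                  numerics = coarse_num()))
  expect_true(all(sol$p_ox >= 0))
  expect_true(all(sol$glucose >= 0))
  expect_true(all(sol$insulin >= 0))
  expect_true(all(sol$p_ox <= 160 + 1e-9))
  expect_true(all(sol$glucose <= 10 + 1e-9))
})

test_that("implicit and explicit schemes agree at steady state", {
  par <- model_params()
  imp <- simulate_scenario(scenario(90, 10, 150, 50), par,
                           numerics_config(n_cells = 48, scheme = "implicit"))
  exp_ <- simulate_scenario(scenario(90, 10, 150, 50), par,
                            numerics_config(n_cells = 48, scheme = "explicit",
                                            dt = 5e-4, t_max = 2000))
  expect_true(imp$steady_state_reached && exp_$steady_state_reached)
  expect_lt(max(abs(imp$p_ox - exp_$p_ox)) / max(imp$p_ox), 5e-3)
  expect_lt(max(abs(imp$glucose - exp_$glucose)) / 10, 5e-3)
})

test_that("instability is detected and reported, not returned silently", {
  # explicit scheme far beyond its stability limit blows up fast
  expect_error(
    simulate_scenario(scenario(90, 10, 150, 50), model_params(),
                      numerics_config(n_cells = 200, scheme = "explicit",
                                      dt = 0.005)),
    "blow-up")
})

test_that("initial fields start at bath values and insulin at zero", {
  sol <- suppressWarnings(
    simulate_scenario(scenario(100, 12, 150, 50), model_params(),
                      coarse_num(t_max = 61, ss_tol = 1e-14),
                      store_times = 0.005))
  snap <- sol$snapshots[[1]]
  # after one step the interior is still essentially at bath values and
  # insulin has accumulated at most one step's worth of secretion
  expect_equal(max(abs(snap[, 2] - 12)), 0, tolerance = 0.05)
  expect_lt(max(snap[, 3]), 1.5 * model_params()$S_max * 0.005)
})

test_that("scenario and numerics inputs are validated", {
  expect_error(scenario(-5, 10, 150, 50), "p_bath")
  expect_error(scenario(800, 10, 150, 50), "p_bath")
  expect_error(scenario(90, -1, 150, 50), "g_bath")
  expect_error(scenario(90, 10, 2500, 50), "islet_diameter")
  expect_error(scenario(90, 10, 150, 6000), "shell_thickness")
  expect_error(numerics_config(dt = 0), "dt")
  expect_error(numerics_config(t_end = 30), "60")
  expect_error(numerics_config(dt = 0.01), "0.005")
  expect_error(numerics_config(ss_tol = 0), "ss_tol")
})

test_that("solution dump writes fields plus a provenance sidecar", {
  sol <- cached("table1_default_coarse",
                simulate_scenario(scenario(160, 10, 500, 50),
                                  numerics = coarse_num()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_solution(sol, path)
  df <- read.csv(path)
  expect_equal(nrow(df), sol$mesh$n_cells)
  expect_equal(df$pO2_mmHg, sol$p_ox)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$scenario$p_bath, 160)
  expect_true(side$diagnostics$steady_state_reached)
})
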