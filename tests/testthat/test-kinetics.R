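par <- model_params()

test_that("survival weight ramps from 0 to 1 around the critical pressure", {
  expect_equal(survival_weight(0, par), 0, tolerance = 1e-10)
  expect_equal(survival_weight(100 * par$p_crit, par), 1, tolerance = 1e-6)
  expect_equal(survival_weight(par$p_crit, par), 0.5)
  p <- seq(0, 1, by = 1e-3)
  expect_true(all(diff(survival_weight(p, par)) >= 0))
  expect_error(survival_weight(-0.1, par), ">= 0")
})

test_that("survival weight converges to the step function as the ramp narrows", {
  p_grid <- seq(0, 0.2, by = 0.004)   # straddles p_crit = 0.07
  step_oracle <- as.numeric(p_grid >= 0.07)
  for (d in c(1e-3, 1e-4, 1e-5)) {
    w <- survival_weight(p_grid, model_params(delta_smooth = d))
    off_grid <- abs(p_grid - 0.07) > d      # outside the shrinking ramp
    expect_equal(w[off_grid], step_oracle[off_grid], tolerance = 1e-6)
  }
})

test_that("oxygen consumption follows gated Michaelis-Menten with glucose demand", {
  expect_equal(oxygen_consumption_rate(0, 10, par), 0)
  # saturation without glucose modulation approaches R_ox_max
  expect_equal(oxygen_consumption_rate(1e6, 0, par), par$R_ox_max,
               tolerance = 1e-4)
  # hyperglycemia raises oxygen demand
  expect_gt(oxygen_consumption_rate(90, 25, par),
            oxygen_consumption_rate(90, 5, par))
  # monotone and bounded in both arguments
  ps <- seq(0, 200, length.out = 50); gs <- seq(0, 30, length.out = 50)
  expect_true(all(diff(oxygen_consumption_rate(ps, 10, par)) >= 0))
  expect_true(all(diff(oxygen_consumption_rate(90, gs, par)) >= 0))
  expect_true(all(oxygen_consumption_rate(ps, 25, par) <=
                    par$R_ox_max * (1 + par$phi_glc_amp)))
  expect_error(oxygen_consumption_rate(-1, 10, par), ">= 0")
})

test_that("glucose consumption is Michaelis-Menten gated by survival", {
  expect_equal(glucose_consumption_rate(90, 0, par), 0)
  expect_equal(glucose_consumption_rate(90, par$K_m_glc, par),
               par$R_glc_max / 2, tolerance = 1e-6)
  expect_equal(glucose_consumption_rate(0, 10, par), 0, tolerance = 1e-10)
  gs <- seq(0, 30, length.out = 50)
  expect_true(all(diff(glucose_consumption_rate(90, gs, par)) >= 0))
  expect_error(glucose_consumption_rate(90, -1, par), ">= 0")
})

test_that("insulin secretion is a Hill law in glucose with an oxygen gate", {
  expect_equal(insulin_secretion_rate(90, 0, par), 0)
  expect_equal(insulin_secretion_rate(500, 1000, par), par$S_max,
               tolerance = 1e-2)
  r <- insulin_secretion_rate(90, c(5, 10, 25), par)
  expect_true(all(diff(r) > 0))
  # secretion shuts down before viability: the gate is 0 well above p_crit
  expect_equal(insulin_secretion_rate(2 * par$p_crit, 25, par), 0)
  expect_gt(par$p_sec_th, par$p_crit)
  ps <- seq(0, 100, length.out = 200)
  expect_true(all(diff(insulin_secretion_rate(ps, 10, par)) >= 0))
  # the gate saturates exactly, so ample oxygen gives identical rates
  expect_identical(insulin_secretion_rate(80, 10, par),
                   insulin_secretion_rate(160, 10, par))
  expect_error(insulin_secretion_rate(90, -2, par), ">= 0")
})

test_that("parameter validation enforces the physical invariants", {
  expect_error(model_params(D_ox_islet = 4000), "D_ox_islet")
  expect_error(model_params(D_glc_gel = 900), "four-fold")
  expect_error(model_params(K_m_ox = -1), "> 0")
  expect_error(model_params(n_s = 0.5), "Hill")
  expect_error(model_params(p_sec_th = 0.05), "p_sec_th")
  p_bad <- unclass(par); p_bad$bogus <- 1
  expect_error(validate_params(p_bad), "unknown parameter")
  p_miss <- unclass(par); p_miss$K_s <- NULL
  expect_error(validate_params(p_miss), "missing parameter")
})

test_that("parameter files round-trip exactly through YAML and JSON", {
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_params(par, path)
    back <- read_params(path)
    expect_equal(unclass(back), unclass(par), tolerance = 1e-12)
  }
  # unknown keys in a file are rejected
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params(par, path)
  cat("mystery_knob: 3\n", file = path, append = TRUE)
  expect_error(read_params(path), "unknown parameter")
})
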