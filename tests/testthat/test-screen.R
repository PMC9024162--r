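test_that("a single-point grid reproduces simulate + metrics exactly", {
  nn <- coarse_num()
  tab <- run_screen(list(p_bath = 160, g_bath = 10, shell_thickness = 50,
                         islet_diameter = 500), numerics = nn)
  expect_equal(nrow(tab), 1)
  sol <- cached("table1_default_coarse",
                simulate_scenario(scenario(160, 10, 500, 50), numerics = nn))
  expect_equal(tab$viability_pct, viability_percent(sol))
  expect_equal(tab$secretion_pct, secretion_percent(sol))
})

test_that("factorial expansion is lexicographic and duplicate-free", {
  g <- list(p_bath = c(90, 160), g_bath = c(5, 10), shell_thickness = 50,
            islet_diameter = 150)
  df <- isletscreen:::expand_scenarios(g)
  expect_equal(nrow(df), 4)
  expect_equal(df$p_bath, c(90, 90, 160, 160))
  expect_equal(df$g_bath, c(5, 10, 5, 10))
  expect_error(isletscreen:::expand_scenarios(
    list(p_bath = c(90, 90), g_bath = 10, shell_thickness = 50,
         islet_diameter = 150)), "duplicate")
  expect_error(isletscreen:::expand_scenarios(
    list(p_bath = 90, oxygen = 1)), "unknown|missing|every axis")
})

test_that("invalid scenarios are rejected before any simulation starts", {
  t0 <- Sys.time()
  expect_error(run_screen(list(p_bath = c(90, 900), g_bath = 10,
                               shell_thickness = 50, islet_diameter = 500)),
               "p_bath")
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
})

test_that("failed scenarios are recorded with their error, never dropped", {
  # a hopeless steady-state tolerance makes the run non-convergent
  nn <- coarse_num(t_max = 60, ss_tol = 1e-15)
  tab <- suppressWarnings(
    run_screen(list(p_bath = c(90, 160), g_bath = 10, shell_thickness = 50,
                    islet_diameter = 500), numerics = nn))
  expect_equal(nrow(tab), 2)
  expect_true(all(is.na(tab$viability_pct)))
  expect_true(all(grepl("steady", tab$error)))
})

test_that("screen tables round-trip exactly through CSV and JSON", {
  nn <- coarse_num()
  tab <- run_screen(list(p_bath = c(90, 160), g_bath = 10,
                         shell_thickness = 50, islet_diameter = 150),
                    numerics = nn)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_screen_table(tab, csv)
  back <- read_screen_table(csv)
  for (col in names(tab))
    expect_identical(back[[col]], as.data.frame(tab)[[col]])
  # CSV header follows the reference table column order
  hdr <- names(read.csv(csv, check.names = FALSE))
  expect_equal(hdr[1:6], c("Oxygen level (mmHg)", "Glucose concentration (mM)",
                           "Hydrogel thickness (um)", "Islet diameter (um)",
                           "Viability (%)", "Insulin secretion (%)"))
  js <- withr::local_tempfile(fileext = ".json")
  write_screen_table(tab, js, format = "json")
  backj <- read_screen_table(js, format = "json")
  expect_equal(backj$viability_pct, tab$viability_pct, tolerance = 1e-12)
  expect_equal(attr(backj, "params_hash"), attr(tab, "params_hash"))
})

test_that("an empty table writes a header-only CSV", {
  tab <- structure(
    data.frame(p_bath_mmHg = numeric(0), g_bath_mM = numeric(0),
               shell_um = numeric(0), islet_diameter_um = numeric(0),
               viability_pct = numeric(0), secretion_pct = numeric(0),
               anoxic_core_radius_um = numeric(0), steady = logical(0),
               flux_residual = numeric(0), error = character(0)),
    class = c("screen_table", "data.frame"))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_screen_table(tab, csv)
  lines <- readLines(csv)
  expect_equal(length(lines), 1)
  expect_match(lines[1], "Oxygen level")
})

test_that("repeated screens are byte-identical", {
  nn <- coarse_num()
  g <- list(p_bath = c(90, 160), g_bath = c(5, 25), shell_thickness = 50,
            islet_diameter = 150)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_screen_table(run_screen(g, numerics = nn), f1)
  write_screen_table(run_screen(g, numerics = nn), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the shipped presets have the documented shapes", {
  expect_equal(nrow(table1_preset()), 16)
  expect_equal(nrow(fig5b_grid()), 16 * 9)
  expect_equal(nrow(fig5c_grid()), 16 * 20)
  expect_equal(nrow(full_screen_grid()), 464)
  ref <- table1_reference()
  expect_true(all(ref$viability_ref >= 0 & ref$viability_ref <= 100))
  # every preset scenario satisfies the scenario invariants
  for (i in seq_len(16))
    expect_s3_class(scenario(ref$p_bath[i], ref$g_bath[i],
                             ref$islet_diameter[i], ref$shell_thickness[i]),
                    "islet_scenario")
})
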