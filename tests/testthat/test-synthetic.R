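test_that("noise-free generation hits its targets through the extraction path", {
  spec <- transient_spec(Fo = 5000, Fm = 25000, V_K_target = 0.15,
                         V_J_target = 0.35, V_I_target = 0.65, noise_cv = 0)
  tr <- generate_transient(spec, seed = 1)
  cp <- extract_cardinals(tr)
  v <- function(f) (cp[[f]] - cp$F_o) / (cp$F_P - cp$F_o)
  expect_lt(abs(v("F_K") - 0.15), 1e-3)
  expect_lt(abs(v("F_J") - 0.35), 1e-3)
  expect_lt(abs(v("F_I") - 0.65), 1e-3)
  expect_equal(value_at(tr, 1000), 25000, tolerance = 1e-6)
  expect_equal(value_at(tr, 0.01), 5000, tolerance = 1e-6)
})

test_that("an L-band target adds a controllable fifth component", {
  spec <- transient_spec(V_L_target = 0.05, V_K_target = 0.15,
                         V_J_target = 0.4, V_I_target = 0.7, noise_cv = 0)
  cp <- extract_cardinals(generate_transient(spec, seed = 1))
  expect_lt(abs((cp$F_L - cp$F_o) / (cp$F_P - cp$F_o) - 0.05), 1e-3)
  expect_error(transient_spec(V_L_target = 0.2, V_K_target = 0.15),
               "V_L_target")
})

test_that("generation is deterministic per seed and varies across seeds", {
  spec <- transient_spec(noise_cv = 0.02)
  a <- generate_transient(spec, seed = 1)
  b <- generate_transient(spec, seed = 1)
  c <- generate_transient(spec, seed = 2)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
})

test_that("raising the K target raises the extracted K level monotonically", {
  got <- vapply(c(0.10, 0.16, 0.22, 0.28), function(vk) {
    spec <- transient_spec(V_K_target = vk, V_J_target = 0.4,
                           V_I_target = 0.7, noise_cv = 0)
    cp <- extract_cardinals(generate_transient(spec, seed = 1))
    (cp$F_K - cp$F_o) / (cp$F_P - cp$F_o)
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("degenerate or unreachable specifications are rejected", {
  expect_error(transient_spec(V_K_target = 0.5, V_J_target = 0.4),
               "V_K_target < V_J_target")
  expect_error(
    generate_transient(transient_spec(component_half_times_ms = c(5, 5, 5, 5)),
                       seed = 1),
    "singular|degenerate")
})

test_that("scenario ground truth carries the injected percent changes exactly", {
  gt <- scenario_ground_truth(flooding_scenario())
  pick <- function(g, p) gt$true_percent_change[gt$group == g & gt$parameter == p]
  expect_equal(pick("D15", "V_J"), 63.49, tolerance = 1e-6)
  expect_equal(pick("D15", "V_K"), 151.37, tolerance = 1e-6)
  expect_equal(pick("D15", "V_L"), 34.43, tolerance = 1e-6)
  expect_equal(pick("D15", "Fv_over_Fm"), -22.13, tolerance = 1e-6)
  expect_equal(pick("D15", "PI_total"), -91.72, tolerance = 1e-6)
  expect_equal(pick("D15", "delta_I_over_Io"), -92.36, tolerance = 0.1)
  expect_equal(pick("D10", "Chl_a_over_b"), -25.06, tolerance = 0.1)
  expect_equal(pick("D15", "Chl_a_over_b"), -37.02, tolerance = 0.1)
  # PI_ABS is implied by the cascade, close to but not at the nominal value
  expect_lt(abs(pick("D15", "PI_ABS") - -96.99), 2)
  # orderings of the injected structure
  expect_gt(abs(pick("D15", "PI_ABS")), abs(pick("D15", "PI_total")))
  expect_gt(abs(pick("D15", "PI_total")), abs(pick("D15", "Fv_over_Fm")))
  expect_gt(pick("D15", "V_K"), pick("D15", "V_J"))
  expect_gt(pick("D15", "V_J"), pick("D15", "V_L"))
})

test_that("a null scenario has identically zero true changes", {
  gt <- scenario_ground_truth(null_scenario())
  expect_equal(max(abs(gt$true_percent_change)), 0)
})

test_that("effect multipliers that push a target past 1 are clipped with warning", {
  sc <- scenario_spec(effects = list(CK = c(), X = c(V_J = 3)), replicates = 2)
  expect_warning(ojipr:::scenario_group_params(sc, "X"), "clipped")
  expect_error(scenario_spec(effects = list(CK = c(), X = c(V_J = -1))), "> 0")
  expect_error(scenario_spec(effects = list(CK = c(), X = c(bogus = 1))),
               "unknown effect")
  expect_error(scenario_spec(effects = list(D5 = c())), "control")
})

test_that("generate_study writes a complete, immediately analysable dataset", {
  d <- withr::local_tempdir()
  generate_study(flooding_scenario(seed = 2), d)
  expect_length(dir(d, pattern = "^transient_"), 20)
  expect_length(dir(d, pattern = "^mr820_"), 20)
  expect_true(all(c("sample_sheet.csv", "pigments.csv", "gas_exchange.csv",
                    "ground_truth.csv") %in% dir(d)))
  sheet <- read_sample_sheet(file.path(d, "sample_sheet.csv"))
  expect_equal(nrow(sheet), 20)
  expect_setequal(unique(sheet$group), c("CK", "D5", "D10", "D15"))
})

test_that("study generation is bit-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sc <- tiny_scenario(seed = 5)
  generate_study(sc, d1)
  generate_study(sc, d2)
  for (f in dir(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})
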