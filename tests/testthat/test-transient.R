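test_that("value_at is exact on grid points and log-linear between them", {
  tr <- generate_transient(transient_spec(noise_cv = 0.05), seed = 3)
  i <- c(1, 57, 333, length(tr$time_ms))
  expect_identical(value_at(tr, tr$time_ms[i]), tr$signal[i])
  # log-midpoint symmetry on a minimal two-point curve
  two <- fluor_transient(c(1, 100), c(100, 300), validate = FALSE)
  expect_equal(value_at(two, 10), 200)
  expect_error(value_at(two, 500), "outside sampled range")
})

test_that("interpolation error on a dense smooth curve is tiny", {
  spec <- transient_spec(noise_cv = 0)
  tr <- generate_transient(spec, seed = 1)
  t_probe <- 10^runif(50, -1.9, 2.9)
  analytic <- spec$Fo + (spec$Fm - spec$Fo) *
    ojipr:::hill_v(spec, t_probe)
  expect_lt(max(abs(value_at(tr, t_probe) - analytic)),
            1e-3 * (spec$Fm - spec$Fo))
})

test_that("value_at preserves monotonicity between bracketing samples", {
  tr <- generate_transient(transient_spec(noise_cv = 0), seed = 1)
  t_probe <- 10^seq(-1.95, 2.95, length.out = 200)
  v <- value_at(tr, t_probe)
  for (k in seq_along(t_probe)) {
    i <- findInterval(t_probe[k], tr$time_ms)
    lo <- min(tr$signal[i], tr$signal[i + 1])
    hi <- max(tr$signal[i], tr$signal[i + 1])
    expect_true(v[k] >= lo - 1e-12 && v[k] <= hi + 1e-12)
  }
})

test_that("cardinal extraction recovers the generator's construction", {
  spec <- transient_spec(Fo = 5000, Fm = 25000, V_K_target = 0.15,
                         V_J_target = 0.35, V_I_target = 0.65, noise_cv = 0)
  cp <- extract_cardinals(generate_transient(spec, seed = 1))
  expect_equal(cp$F_o, 5000, tolerance = 1e-3)
  expect_equal(cp$F_P, 25000, tolerance = 1e-3)
  expect_length(cp$qc, 0)
})

test_that("a flat curve yields equal cardinals and a QC flag", {
  flat <- fluor_transient(10^seq(-2, 3, length.out = 100), rep(7000, 100))
  cp <- extract_cardinals(flat)
  expect_equal(unname(unlist(cp[c("F_o", "F_L", "F_K", "F_J", "F_I", "F_P")])),
               rep(7000, 6))
  expect_true("no variable fluorescence" %in% cp$qc)
})

test_that("fm_rule = curve_max picks the peak of early-peaking curves", {
  tt <- 10^seq(-2, 3, length.out = 200)
  peak <- 25000 * exp(-0.5 * ((log10(tt) - log10(800)) / 1.2)^2) + 5000
  tr <- fluor_transient(tt, peak)
  cfg_max <- run_config(fm_rule = "curve_max")
  cp_max <- extract_cardinals(tr, cfg_max)
  cp_time <- extract_cardinals(tr, run_config())
  expect_equal(cp_max$F_P, max(peak))
  expect_gte(cp_max$F_P, cp_time$F_P)
})

test_that("extraction errors name the missing cardinal point", {
  short <- fluor_transient(10^seq(-2, 2, length.out = 50),
                           seq(5000, 20000, length.out = 50))
  expect_error(extract_cardinals(short), "P time \\(1000 ms\\)")
})

test_that("extraction commutes with positive rescaling of the signal", {
  tr <- generate_transient(transient_spec(), seed = 9)
  tr3 <- tr; tr3$signal <- tr$signal * 3.7
  cp <- extract_cardinals(tr); cp3 <- extract_cardinals(tr3)
  for (f in c("F_o", "F_L", "F_K", "F_J", "F_I", "F_P"))
    expect_equal(cp3[[f]], 3.7 * cp[[f]], tolerance = 1e-12)
})
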