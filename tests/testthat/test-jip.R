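test_that("the worked cardinal set reproduces the hand-computed cascade", {
  cp <- make_cardinals(5000, 6000, 8000, 12000, 18000, 25000)
  jp <- jip_parameters(cp)
  # frozen values computed by hand from the flux-ratio definitions
  expect_equal(jp$Fv_over_Fm, 0.8, tolerance = 1e-9)
  expect_equal(jp$M_o, 0.6, tolerance = 1e-9)
  expect_equal(jp$V_J, 0.35, tolerance = 1e-9)
  expect_equal(jp$psi_Eo, 0.65, tolerance = 1e-9)
  expect_equal(jp$phi_Eo, 0.52, tolerance = 1e-9)
  expect_equal(jp$RC_per_ABS, 0.8 * 0.35 / 0.6, tolerance = 1e-9)
  expect_equal(jp$ABS_per_RC, 0.6 / (0.35 * 0.8), tolerance = 1e-9)
  expect_equal(jp$TRo_per_RC, 0.6 / 0.35, tolerance = 1e-9)
  expect_equal(jp$DIo_per_RC, 0.6 / (0.35 * 0.8) - 0.6 / 0.35, tolerance = 1e-9)
  expect_equal(jp$delta_Ro, 0.35 / 0.65, tolerance = 1e-9)
  expect_equal(jp$PI_ABS, (0.8 * 0.35 / 0.6) * 4 * (0.65 / 0.35), tolerance = 1e-9)
  expect_equal(jp$PI_total, jp$PI_ABS * (0.35 / 0.65) / (1 - 0.35 / 0.65),
               tolerance = 1e-9)
})

test_that("Fv/Fm is forced by definition", {
  cp <- make_cardinals(6000, 7000, 8000, 9000, 10000, 12000)
  expect_equal(jip_parameters(cp)$Fv_over_Fm, 0.5, tolerance = 1e-12)
})

test_that("the cascade is scale-free: rescaled cardinals give identical fields", {
  sets <- random_cardinals(25, seed = 7)
  for (cp in sets) {
    jp <- jip_parameters(cp)
    cp3 <- cp
    for (f in c("F_o", "F_L", "F_K", "F_J", "F_I", "F_P")) cp3[[f]] <- 3 * cp[[f]]
    jp3 <- jip_parameters(cp3)
    for (f in setdiff(names(jp), "qc"))
      expect_equal(jp3[[f]], jp[[f]], tolerance = 1e-12)
  }
})

test_that("internal flux identities hold exactly", {
  for (cp in random_cardinals(50, seed = 13)) {
    jp <- jip_parameters(cp)
    expect_equal(jp$DIo_per_RC, jp$ABS_per_RC - jp$TRo_per_RC, tolerance = 1e-12)
    expect_equal(jp$ETo_per_RC, jp$TRo_per_RC * jp$psi_Eo, tolerance = 1e-12)
    expect_equal(jp$RC_per_ABS, 1 / jp$ABS_per_RC, tolerance = 1e-12)
    expect_equal(jp$phi_Eo, jp$Fv_over_Fm * (1 - jp$V_J), tolerance = 1e-12)
    if (!is.na(jp$PI_total))
      expect_equal(jp$PI_total, jp$PI_ABS * jp$delta_Ro / (1 - jp$delta_Ro),
                   tolerance = 1e-12)
  }
})

test_that("PI_ABS rises with phi_Po and falls with V_J", {
  base <- function(phi, vJ) {
    Fo <- 5000; Fm <- Fo / (1 - phi); Fv <- Fm - Fo
    jip_parameters(make_cardinals(Fo, NA, Fo + 0.12 * Fv, Fo + vJ * Fv,
                                  Fo + 0.75 * Fv, Fm))$PI_ABS
  }
  phis <- seq(0.55, 0.85, length.out = 8)
  pis <- vapply(phis, base, numeric(1), vJ = 0.4)
  expect_true(all(diff(pis) > 0))
  vjs <- seq(0.2, 0.7, length.out = 8)
  pis <- vapply(vjs, function(v) base(0.8, v), numeric(1))
  expect_true(all(diff(pis) < 0))
})

test_that("degenerate inputs are rejected or flagged, not silently computed", {
  expect_error(jip_parameters(make_cardinals(5000, 6000, 8000, 25000, 25000, 25000)),
               "division by zero")                       # V_J = 1
  jp <- jip_parameters(make_cardinals(5000, 6000, 8000, 18000, 12000, 25000))
  expect_true(is.na(jp$PI_total))                        # V_I < V_J
  expect_true(any(grepl("delta_Ro", jp$qc)))
  expect_error(jip_parameters(make_cardinals(5000, 5000, 5000, 5000, 5000, 4000)),
               "F_m")
})

test_that("jip_table produces one row per sample and parameter, excluding bad files", {
  d <- withr::local_tempdir()
  generate_study(flooding_scenario(seed = 21), d)
  sheet <- read_sample_sheet(file.path(d, "sample_sheet.csv"))
  tab <- jip_table(sheet)
  expect_equal(nrow(tab), 4 * 5 * 6)
  expect_setequal(unique(tab$parameter),
                  c("V_L", "V_K", "V_J", "Fv_over_Fm", "PI_ABS", "PI_total"))
  # corrupt one curve: that sample is dropped with a log entry, rest survive
  writeLines("time_ms,signal\n1,2", sheet$curve_path[3])
  expect_message(tab2 <- jip_table(sheet), "excluded")
  expect_equal(nrow(tab2), 19 * 6)
})

test_that("with no injected effect, group means agree within noise", {
  d <- withr::local_tempdir()
  generate_study(null_scenario(seed = 31), d)
  tab <- jip_table(read_sample_sheet(file.path(d, "sample_sheet.csv")))
  vj <- tab[tab$parameter == "V_J", ]
  means <- tapply(vj$value, vj$group, mean)
  sds <- tapply(vj$value, vj$group, sd)
  expect_lt(max(means) - min(means), 4 * max(sds))
})
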