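test_that("every normalisation window pins its endpoints at 0 and 1", {
  tr <- generate_transient(transient_spec(), seed = 5)
  cp <- extract_cardinals(tr)
  for (w in c("O-P", "O-J", "O-K")) {
    nc <- normalize_curve(tr, cp, window = w)
    expect_lt(abs(nc$V[1]), 1e-9)
    expect_lt(abs(nc$V[nrow(nc)] - 1), 1e-9)
  }
})

test_that("relative variable fluorescence matches the defining ratios", {
  cp <- make_cardinals(5000, 6000, 8000, 12000, 18000, 25000)
  rvf <- relative_variable_fluorescence(cp)
  expect_equal(rvf$V_L, 1000 / 3000, tolerance = 1e-12)
  expect_equal(rvf$V_K, 3000 / 7000, tolerance = 1e-12)
  expect_equal(rvf$V_J, 7000 / 20000, tolerance = 1e-12)
  expect_equal(rvf$V_I, 13000 / 20000, tolerance = 1e-12)
  # zero and endpoint cases
  expect_equal(relative_variable_fluorescence(
    make_cardinals(5000, 5000, 8000, 12000, 18000, 25000))$V_L, 0)
  expect_equal(relative_variable_fluorescence(
    make_cardinals(5000, 6000, 8000, 25000, 25000, 25000))$V_J, 1)
  expect_error(relative_variable_fluorescence(
    make_cardinals(5000, 5000, 5000, 12000, 18000, 25000)), "O-K")
})

test_that("normalisation is invariant to scaling and common shifts", {
  tr <- generate_transient(transient_spec(), seed = 11)
  nc <- normalize_curve(tr, extract_cardinals(tr))
  sc <- tr; sc$signal <- tr$signal * 7.3
  nc_sc <- normalize_curve(sc, extract_cardinals(sc))
  expect_equal(nc_sc$V, nc$V, tolerance = 1e-12)
  sh <- tr; sh$signal <- tr$signal + 1234.5
  nc_sh <- normalize_curve(sh, extract_cardinals(sh))
  expect_equal(nc_sh$V, nc$V, tolerance = 1e-12)
  # and so are the band ratios
  rvf <- relative_variable_fluorescence(extract_cardinals(tr))
  rvf_sc <- relative_variable_fluorescence(extract_cardinals(sc))
  rvf_sh <- relative_variable_fluorescence(extract_cardinals(sh))
  for (f in c("V_L", "V_K", "V_J", "V_I")) {
    expect_equal(rvf_sc[[f]], rvf[[f]], tolerance = 1e-12)
    expect_equal(rvf_sh[[f]], rvf[[f]], tolerance = 1e-12)
  }
})

test_that("normalisation refuses non-inducing curves", {
  flat <- fluor_transient(10^seq(-2, 3, length.out = 100), rep(7000, 100))
  cp <- extract_cardinals(flat)
  expect_error(normalize_curve(flat, cp), "non-inducing")
})

test_that("V from cardinals agrees with reading the normalised curve", {
  tr <- generate_transient(transient_spec(noise_cv = 0), seed = 2)
  cp <- extract_cardinals(tr)
  rvf <- relative_variable_fluorescence(cp)
  nc <- normalize_curve(tr, cp, window = "O-P")
  v_at <- function(t) approx(log10(nc$time_ms), nc$V, xout = log10(t))$y
  expect_equal(v_at(2), rvf$V_J, tolerance = 1e-6)
  expect_equal(v_at(30), rvf$V_I, tolerance = 1e-6)
})

test_that("difference kinetics: self-difference is zero, n=1 is pointwise", {
  tr1 <- generate_transient(transient_spec(), seed = 1)
  tr2 <- generate_transient(transient_spec(), seed = 2)
  n1 <- normalize_curve(tr1, extract_cardinals(tr1), window = "O-J")
  n2 <- normalize_curve(tr2, extract_cardinals(tr2), window = "O-J")
  expect_equal(max(abs(difference_kinetics(list(n1, n2), list(n1, n2))$dV)), 0)
  dv <- difference_kinetics(n1, n2)
  expect_equal(dv$dV, n1$V - n2$V, tolerance = 1e-12)
  nP <- normalize_curve(tr1, extract_cardinals(tr1), window = "O-P")
  expect_error(difference_kinetics(n1, nP), "window mismatch")
})

test_that("an injected K-band rise shows as a positive dV_O-J peak near 0.3 ms", {
  sc <- flooding_scenario(seed = 4)
  ck <- ojipr:::scenario_group_params(sc, "CK")$spec
  d15 <- ojipr:::scenario_group_params(sc, "D15")$spec
  mk <- function(spec, seed) {
    tr <- generate_transient(spec, seed = seed)
    normalize_curve(tr, extract_cardinals(tr), window = "O-J")
  }
  dv <- difference_kinetics(lapply(1:3, function(i) mk(d15, i)),
                            lapply(4:6, function(i) mk(ck, i)))
  expect_gt(approx(log10(dv$time_ms), dv$dV, xout = log10(0.3))$y, 0.2)
  t_peak <- dv$time_ms[which.max(dv$dV)]
  expect_gt(t_peak, 0.1); expect_lt(t_peak, 1.5)
})
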