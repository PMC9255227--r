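test_that("identical groups give F = 0, p = 1", {
  res <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
})

test_that("perfect separation with zero within-group variance is flagged", {
  res <- one_way_anova(c(0, 0, 0, 1, 1, 1), rep(c("a", "b"), each = 3))
  expect_true(is.infinite(res$F))
  expect_equal(res$p, 0)
  expect_equal(res$flag, "degenerate")
  res0 <- one_way_anova(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res0$p, 1)
  expect_equal(res0$flag, "no variance")
})

test_that("ANOVA agrees with an independent sum-of-squares oracle", {
  set.seed(99)
  for (i in 1:20) {
    value <- rnorm(20, mean = rep(runif(4, 0, 3), each = 5))
    group <- rep(letters[1:4], each = 5)
    got <- one_way_anova(value, group)
    want <- anova_oracle(value, group)
    expect_equal(got$F, want$F, tolerance = 1e-9)
    expect_equal(got$MSE, want$MSE, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
    expect_equal(got$df_err, 16)
  }
})

test_that("LSD letters: near groups share, far groups differ", {
  set.seed(1)
  near <- c(rnorm(5, 10, 1), rnorm(5, 10.2, 1))
  g2 <- rep(c("a", "b"), each = 5)
  lsd <- lsd_posthoc(near, g2)
  expect_equal(length(unique(lsd$letter)), 1)
  far <- c(rnorm(5, 10, 0.5), rnorm(5, 20, 0.5))
  lsd2 <- lsd_posthoc(far, g2)
  expect_equal(length(unique(lsd2$letter)), 2)
  expect_equal(lsd2$letter, c("a", "b"))     # ordered by descending mean
  expect_equal(lsd2$group[1], "b")
})

test_that("unequal group sizes fall back to the harmonic-mean LSD, flagged", {
  set.seed(2)
  value <- c(rnorm(5, 10), rnorm(8, 12))
  group <- c(rep("a", 5), rep("b", 8))
  lsd <- lsd_posthoc(value, group, protected = FALSE)
  expect_match(attr(lsd, "flag"), "harmonic")
  aovr <- one_way_anova(value, group)
  n_h <- 2 / (1 / 5 + 1 / 8)
  expect_equal(attr(lsd, "LSD"),
               qt(0.975, aovr$df_err) * sqrt(2 * aovr$MSE / n_h),
               tolerance = 1e-12)
})

test_that("protection gates letters on the ANOVA F test", {
  set.seed(3)
  value <- rnorm(20)                          # pure null
  group <- rep(letters[1:4], each = 5)
  aovr <- one_way_anova(value, group)
  lsd_p <- lsd_posthoc(value, group, anova = aovr, protected = TRUE)
  if (aovr$p >= 0.05) expect_equal(unique(lsd_p$letter), "a")
  lsd_u <- lsd_posthoc(value, group, anova = aovr, protected = FALSE)
  expect_true(all(nchar(lsd_u$letter) == 1))
})

test_that("percent change is signed, zero at control and scale-equivariant", {
  tab <- tibble::tibble(sample_id = sprintf("s%d", 1:12),
                        group = rep(c("CK", "T1", "T2"), each = 4),
                        replicate = rep(1:4, 3),
                        parameter = "p",
                        value = c(rep(10, 4), rep(5, 4), rep(13, 4)))
  pc <- percent_change(tab, control = "CK")
  expect_equal(pc$percent_change[pc$group == "T1"], -50)
  expect_equal(pc$percent_change[pc$group == "CK"], 0)
  expect_equal(pc$percent_change[pc$group == "T2"], 30)
  tab_scaled <- tab; tab_scaled$value <- tab$value * 17
  expect_equal(percent_change(tab_scaled, "CK")$percent_change,
               pc$percent_change, tolerance = 1e-12)
  expect_error(percent_change(tab, control = "XX"), "not present")
})

test_that("group_summary assembles letters, F, p and percent change", {
  set.seed(4)
  tab <- tibble::tibble(
    sample_id = sprintf("s%d", 1:20),
    group = rep(c("CK", "D5", "D10", "D15"), each = 5),
    replicate = rep(1:5, 4),
    parameter = "PI_ABS",
    value = rnorm(20, mean = rep(c(3, 2.4, 1, 0.1), each = 5), sd = 0.1))
  gs <- group_summary(tab, control = "CK")
  expect_setequal(names(gs), c("parameter", "group", "n", "mean", "sd",
                               "letter", "F", "p", "percent_change"))
  expect_equal(gs$percent_change[gs$group == "CK"], 0)
  expect_false(gs$letter[gs$group == "CK"] == gs$letter[gs$group == "D15"])
  expect_lt(gs$percent_change[gs$group == "D15"], -90)
})
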