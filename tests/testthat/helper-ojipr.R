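# build a cardinal_points object directly from fluorescence levels
make_cardinals <- function(F_o, F_L = NA, F_K, F_J, F_I, F_P) {
  structure(list(F_o = F_o, F_L = if (is.na(F_L)) (F_o + F_K) / 2 else F_L,
                 F_K = F_K, F_J = F_J, F_I = F_I, F_P = F_P,
                 times_ms = c(O = 0.01, L = 0.15, K = 0.3, J = 2, I = 30,
                              P = 1000),
                 fm_rule = "at_P_time", qc = character()),
            class = "cardinal_points")
}

# random valid cardinal sets: F_o < F_L < F_K < F_J < F_I < F_P
random_cardinals <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    F_o <- runif(1, 2000, 9000)
    Fv <- runif(1, 1, 4) * F_o
    v <- sort(runif(4, 0.02, 0.98))           # V at L, K, J, I on O-P scale
    make_cardinals(F_o, F_o + v[1] * Fv, F_o + v[2] * Fv, F_o + v[3] * Fv,
                   F_o + v[4] * Fv, F_o + Fv)
  })
}

# independent brute-force transcription of the Strasser JIP-test formulas,
# written directly from the fluorescence levels (no shared code with the
# package implementation)
jip_oracle <- function(F_o, F_K, F_J, F_I, F_m) {
  phiPo <- 1 - F_o / F_m
  VJ <- (F_J - F_o) / (F_m - F_o)
  VI <- (F_I - F_o) / (F_m - F_o)
  Mo <- 4 * (F_K - F_o) / (F_m - F_o)
  psiEo <- 1 - VJ
  dRo <- (1 - VI) / (1 - VJ)
  ABS_RC <- Mo * (1 / VJ) * (1 / phiPo)
  TR_RC <- Mo * (1 / VJ)
  ET_RC <- Mo * (1 / VJ) * psiEo
  PI_abs <- (phiPo * VJ / Mo) * (phiPo / (1 - phiPo)) * (psiEo / (1 - psiEo))
  list(Fv_over_Fm = phiPo, M_o = Mo, V_J = VJ, V_I = VI, psi_Eo = psiEo,
       phi_Eo = phiPo * psiEo, delta_Ro = dRo, phi_Ro = phiPo * psiEo * dRo,
       ABS_per_RC = ABS_RC, TRo_per_RC = TR_RC, ETo_per_RC = ET_RC,
       DIo_per_RC = ABS_RC - TR_RC, RC_per_ABS = phiPo * VJ / Mo,
       PI_ABS = PI_abs, PI_total = PI_abs * dRo / (1 - dRo))
}

# independent sum-of-squares one-way ANOVA (no aov/lm)
anova_oracle <- function(value, group) {
  group <- factor(group)
  gm <- mean(value)
  means <- tapply(value, group, mean)
  ns <- tapply(value, group, length)
  SSB <- sum(ns * (means - gm)^2)
  SSW <- sum((value - means[group])^2)
  df_b <- nlevels(group) - 1
  df_e <- length(value) - nlevels(group)
  MSB <- SSB / df_b
  MSE <- SSW / df_e
  list(F = MSB / MSE, MSE = MSE, p = pf(MSB / MSE, df_b, df_e, lower.tail = FALSE))
}

# a tiny 2-group x 2-rep scenario for fast pipeline tests
tiny_scenario <- function(seed = 1) {
  scenario_spec(effects = list(CK = c(), TR = c(V_J = 1.3, PI_total = 0.5)),
                replicates = 2, seed = seed)
}
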