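#' Study scenario: treatment groups with injected effects
#'
#' A scenario describes a complete synthetic study: a control group plus
#' treatment groups whose physiology differs from the control by known
#' multiplicative effects. Effects are expressed on the scale of the
#' *measured* parameters -- `Fv_over_Fm`, `V_L`, `V_K`, `V_J` (the
#' band-specific relative variable fluorescence values), `PI_total`,
#' `delta_I_over_Io`, `Pn`, `Gs`, `Tr`, `Ci`, `Chl_a`, `Chl_b` -- and are
#' translated internally into generator parameters: the O-P-scale targets
#' follow from the band definitions (`v_K = V_K v_J`, `v_L = V_L v_K`), F_m
#' follows from Fv/Fm at fixed F_o, and the I-step target is solved from the
#' requested PI_total through the JIP cascade. PI_ABS is then fully
#' determined by the other injections and is reported in the ground truth
#' rather than being independently settable.
#'
#' @param effects Named list: one entry per group, each a named numeric
#'   vector of multipliers (missing entries default to 1). Must include a
#'   control group named `control` with all-1 effects.
#' @param replicates Replicates per group.
#' @param seed Integer seed driving all randomness of the study.
#' @param control Name of the control group (default `"CK"`).
#' @param baseline Control-group physiology; see [scenario_baseline()].
#' @return An object of class `scenario_spec`.
#' @seealso [flooding_scenario()], [null_scenario()], [generate_study()]
#' @export
scenario_spec <- function(effects, replicates = 5L, seed = 1L,
                          control = "CK", baseline = scenario_baseline()) {
  if (!control %in% names(effects))
    stop("effects must include the control group '", control, "'")
  known <- c("Fv_over_Fm", "V_L", "V_K", "V_J", "PI_total", "delta_I_over_Io",
             "Pn", "Gs", "Tr", "Ci", "Chl_a", "Chl_b")
  effects <- lapply(effects, function(e) {
    e <- unlist(e)
    bad <- setdiff(names(e), known)
    if (length(bad)) stop("unknown effect multiplier(s): ", paste(bad, collapse = ", "))
    if (any(e <= 0)) stop("all effect multipliers must be > 0")
    full <- setNames(rep(1, length(known)), known)
    full[names(e)] <- e
    full
  })
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(effects = effects, replicates = as.integer(replicates),
                 seed = as.integer(seed), control = control,
                 baseline = baseline),
            class = "scenario_spec")
}

#' Baseline (control) physiology for synthetic studies
#'
#' Values typical of healthy, dark-adapted broadleaf material: Fv/Fm near
#' 0.8, a J step near the middle of the rise, K and L bands low, gas
#' exchange and pigment levels in the usual range for a well-watered
#' seedling. The vignette discusses each choice.
#'
#' @param Fo,Fv_over_Fm Minimal fluorescence (a.u.) and maximum PSII yield.
#' @param V_L,V_K,V_J Band-scale relative variable fluorescence values.
#' @param V_I_op I-step target on the O-P scale.
#' @param mr820 An [mr820_spec()] for the control MR820 curve.
#' @param Pn,Gs,Tr,Ci Gas exchange: umol CO2 m-2 s-1, mol H2O m-2 s-1,
#'   mmol H2O m-2 s-1, umol mol-1.
#' @param Chl_a,Chl_b Pigment contents, mg per g fresh mass.
#' @param noise_cv Replicate noise CV for transients, pigments and gas
#'   exchange.
#' @param fresh_mass_g,extract_volume_mL,dilution_factor Pigment assay setup.
#' @return A named list.
#' @export
scenario_baseline <- function(Fo = 5000, Fv_over_Fm = 0.8,
                              V_L = 0.28, V_K = 0.35, V_J = 0.45,
                              V_I_op = 0.775,
                              mr820 = mr820_spec(),
                              Pn = 15, Gs = 0.4, Tr = 5, Ci = 280,
                              Chl_a = 1.8, Chl_b = 0.6,
                              noise_cv = 0.02,
                              fresh_mass_g = 0.1, extract_volume_mL = 10,
                              dilution_factor = 1) {
  list(Fo = Fo, Fv_over_Fm = Fv_over_Fm, V_L = V_L, V_K = V_K, V_J = V_J,
       V_I_op = V_I_op, mr820 = mr820, Pn = Pn, Gs = Gs, Tr = Tr, Ci = Ci,
       Chl_a = Chl_a, Chl_b = Chl_b, noise_cv = noise_cv,
       fresh_mass_g = fresh_mass_g, extract_volume_mL = extract_volume_mL,
       dilution_factor = dilution_factor)
}

#' The flooding preset
#'
#' Four groups -- control (CK) and 5, 10 and 15 days of flooding (D5, D10,
#' D15) -- with effect directions and magnitudes of a progressive flooding
#' response of a woody seedling: the L, K and J bands rise (antenna
#' connectivity loss, OEC damage, acceptor-side block) with the reported
#' relative increases, Fv/Fm is stable until a late moderate decline, the
#' performance index and the PSI amplitude collapse nearly completely by day
#' 15, chlorophyll (a more than b) is degraded, and stomata close (Pn, Gs,
#' Tr down; Ci dips at day 10 then rebounds under non-stomatal limitation).
#'
#' @param replicates Replicates per group (default 5).
#' @param seed Study seed.
#' @return A [scenario_spec()].
#' @export
flooding_scenario <- function(replicates = 5L, seed = 1L) {
  scenario_spec(effects = list(
    CK = c(),
    D5 = c(V_J = 1.1639, V_K = 1.1986, V_L = 1.0246,
           PI_total = 0.60, delta_I_over_Io = 0.60,
           Pn = 0.95, Gs = 0.95, Tr = 0.95, Ci = 0.98,
           Chl_a = 0.95, Chl_b = 0.97),
    D10 = c(Fv_over_Fm = 0.97, V_J = 1.4398, V_K = 1.8425, V_L = 1.1086,
            PI_total = 0.30, delta_I_over_Io = 0.30,
            Pn = 0.60, Gs = 0.55, Tr = 0.60, Ci = 0.80,
            Chl_a = 0.7194, Chl_b = 0.96),
    D15 = c(Fv_over_Fm = 0.7787, V_J = 1.6349, V_K = 2.5137, V_L = 1.3443,
            PI_total = 0.0828, delta_I_over_Io = 0.0764,
            Pn = 0.45, Gs = 0.40, Tr = 0.45, Ci = 0.92,
            Chl_a = 0.5479, Chl_b = 0.87)),
    replicates = replicates, seed = seed)
}

#' A null scenario: groups with no injected effect
#'
#' Same four group labels as the flooding preset but all multipliers 1;
#' groups are statistically indistinguishable. Used for type-I-error
#' calibration of the LSD letters.
#'
#' @inheritParams flooding_scenario
#' @return A [scenario_spec()].
#' @export
null_scenario <- function(replicates = 5L, seed = 1L) {
  scenario_spec(effects = list(CK = c(), D5 = c(), D10 = c(), D15 = c()),
                replicates = replicates, seed = seed)
}

# translate one group's multipliers into generator parameters + true values
scenario_group_params <- function(scenario, group) {
  e <- scenario$effects[[group]]
  b <- scenario$baseline
  clip01 <- function(x, what) {
    if (x >= 1) {
      warning(what, " target clipped below 1 for group ", group)
      x <- 1 - 1e-6
    }
    x
  }
  phi <- clip01(b$Fv_over_Fm * e[["Fv_over_Fm"]], "Fv/Fm")
  V_J <- clip01(b$V_J * e[["V_J"]], "V_J")
  V_K <- clip01(b$V_K * e[["V_K"]], "V_K")
  V_L <- clip01(b$V_L * e[["V_L"]], "V_L")
  v_K_op <- V_K * V_J
  v_L_op <- V_L * v_K_op
  Fm <- b$Fo / (1 - phi)
  # baseline cascade fixes PI_total0; the group's V_I follows from PI_total
  pi_abs <- function(phi, vJ, vKop) phi^2 * (1 - vJ) / (4 * vKop * (1 - phi))
  phi0 <- b$Fv_over_Fm; vJ0 <- b$V_J; vK0_op <- b$V_K * b$V_J
  d0 <- (1 - b$V_I_op) / (1 - vJ0)
  PI_ABS0 <- pi_abs(phi0, vJ0, vK0_op)
  PI_total0 <- PI_ABS0 * d0 / (1 - d0)
  PI_ABS_g <- pi_abs(phi, V_J, v_K_op)
  PI_total_g <- PI_total0 * e[["PI_total"]]
  x <- PI_total_g / PI_ABS_g
  d_g <- x / (1 + x)
  v_I_op <- 1 - d_g * (1 - V_J)
  if (v_I_op <= V_J || v_I_op >= 1)
    stop("PI_total multiplier for group ", group,
         " implies an I-step target outside (V_J, 1)")
  mr <- scenario$baseline$mr820
  mr$delta_I <- mr$delta_I * e[["delta_I_over_Io"]]
  list(spec = transient_spec(Fo = b$Fo, Fm = Fm,
                             V_K_target = v_K_op, V_J_target = V_J,
                             V_I_target = v_I_op, V_L_target = v_L_op,
                             noise_cv = b$noise_cv),
       mr820 = mr,
       truth = c(Fv_over_Fm = phi, V_L = V_L, V_K = V_K, V_J = V_J,
                 PI_ABS = PI_ABS_g,
                 PI_total = PI_ABS_g * d_g / (1 - d_g),
                 delta_I_over_Io = mr820_true_ratio(mr),
                 Pn = b$Pn * e[["Pn"]], Gs = b$Gs * e[["Gs"]],
                 Tr = b$Tr * e[["Tr"]], Ci = b$Ci * e[["Ci"]],
                 Chl_a = b$Chl_a * e[["Chl_a"]], Chl_b = b$Chl_b * e[["Chl_b"]],
                 Chl_ab = b$Chl_a * e[["Chl_a"]] + b$Chl_b * e[["Chl_b"]],
                 Chl_a_over_b = (b$Chl_a * e[["Chl_a"]]) / (b$Chl_b * e[["Chl_b"]])))
}

#' Ground truth of a scenario
#'
#' The noise-free value of every reported parameter per group, plus the true
#' percent change versus the control. PI_ABS is derived through the JIP
#' cascade from the injected Fv/Fm, V_J and V_K, so its change is implied
#' rather than injected.
#'
#' @param scenario A [scenario_spec()].
#' @return A tibble `group, parameter, true_value, true_percent_change`.
#' @export
scenario_ground_truth <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  truths <- lapply(names(scenario$effects),
                   function(g) scenario_group_params(scenario, g)$truth)
  names(truths) <- names(scenario$effects)
  ctrl <- truths[[scenario$control]]
  dplyr::bind_rows(lapply(names(truths), function(g) {
    tibble::tibble(group = g, parameter = names(truths[[g]]),
                   true_value = unname(truths[[g]]),
                   true_percent_change =
                     100 * (unname(truths[[g]]) - unname(ctrl)) / unname(ctrl))
  }))
}

#' Generate a complete synthetic study on disk
#'
#' Writes, for every group and replicate, an OJIP transient file and an
#' MR820 curve file; one pigment-record file and one gas-exchange file for
#' the whole study; the sample sheet tying everything together; and the
#' ground-truth table (`ground_truth.csv`). The dataset is immediately
#' analysable with [analyze_study()]. All randomness is derived from `seed`
#' (one sub-seed per sample), so identical calls are bit-identical on disk.
#'
#' @param scenario A [scenario_spec()].
#' @param dir Output directory (created if needed).
#' @param seed Optional override of `scenario$seed`.
#' @return The path to the sample sheet, invisibly. The directory also gains
#'   `pigments.csv`, `gas_exchange.csv` and `ground_truth.csv`.
#' @export
generate_study <- function(scenario, dir, seed = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  seed <- as.integer(seed %||% scenario$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- names(scenario$effects)
  reps <- scenario$replicates
  b <- scenario$baseline
  params <- lapply(groups, function(g) scenario_group_params(scenario, g))
  names(params) <- groups

  sheet <- list(); pig <- list(); gas <- list()
  idx <- 0L
  base_seed <- (seed %% 1000000L) * 1000L
  for (g in groups) {
    pg <- params[[g]]
    for (r in seq_len(reps)) {
      idx <- idx + 1L
      sid <- sprintf("%s_r%d", g, r)
      s_tr <- base_seed + 2L * idx
      s_mr <- base_seed + 2L * idx + 1L
      tr <- generate_transient(pg$spec, seed = s_tr, sample_id = sid,
                               group = g, replicate = r)
      mr <- generate_mr820(pg$mr820, seed = s_mr, sample_id = sid,
                           group = g, replicate = r)
      tr_file <- sprintf("transient_%s.csv", sid)
      mr_file <- sprintf("mr820_%s.csv", sid)
      write_transient(tr, file.path(dir, tr_file))
      write_mr820(mr, file.path(dir, mr_file))
      sheet[[idx]] <- data.frame(sample_id = sid, group = g, replicate = r,
                                 curve_path = tr_file, mr820_path = mr_file)
      # pigment record: jitter the true concentrations, invert to absorbances
      set.seed(base_seed + 50000L + idx)
      conc <- c(pg$truth[["Chl_a"]], pg$truth[["Chl_b"]]) *
        (1 + b$noise_cv * rnorm(2))
      C_ugml <- conc * 1000 * b$fresh_mass_g /
        (b$extract_volume_mL * b$dilution_factor)
      A <- solve(porra_coefficients()$M, C_ugml)
      pig[[idx]] <- data.frame(sample_id = sid, group = g, replicate = r,
                               A_663 = A[1], A_646 = A[2],
                               dilution_factor = b$dilution_factor,
                               fresh_mass_g = b$fresh_mass_g,
                               extract_volume_mL = b$extract_volume_mL)
      set.seed(base_seed + 70000L + idx)
      ge <- c(pg$truth[["Pn"]], pg$truth[["Gs"]], pg$truth[["Tr"]],
              pg$truth[["Ci"]]) * (1 + b$noise_cv * rnorm(4))
      gas[[idx]] <- data.frame(sample_id = sid, group = g, replicate = r,
                               Pn = ge[1], Gs = ge[2], Tr = ge[3], Ci = ge[4])
    }
  }
  sheet_path <- file.path(dir, "sample_sheet.csv")
  write_sample_sheet(do.call(rbind, sheet), sheet_path)
  write_records(do.call(rbind, pig), file.path(dir, "pigments.csv"))
  write_records(do.call(rbind, gas), file.path(dir, "gas_exchange.csv"))
  gt <- scenario_ground_truth(scenario)
  gt_out <- as.data.frame(gt)
  gt_out$true_value <- sprintf("%.15g", gt_out$true_value)
  gt_out$true_percent_change <- sprintf("%.15g", gt_out$true_percent_change)
  write.table(gt_out, file.path(dir, "ground_truth.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  ojip_log("simulate", sprintf("wrote %d samples (%d groups x %d reps) to %s",
                               idx, length(groups), reps, dir))
  invisible(sheet_path)
}
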