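#' JIP-test parameter cascade
#'
#' Derives the standard JIP-test quantities from one set of cardinal points,
#' following Strasser's energy-flux framework:
#' \itemize{
#'   \item maximum PSII photochemical efficiency
#'     \eqn{\varphi_{Po} = F_v/F_m = 1 - F_o/F_m}
#'   \item initial relative rise \eqn{M_o = 4 (F_K - F_o)/(F_m - F_o)}
#'     (per ms; F_K is the 0.3 ms level)
#'   \item \eqn{\psi_{Eo} = 1 - V_J},
#'     \eqn{\varphi_{Eo} = \varphi_{Po}\,\psi_{Eo}},
#'     \eqn{\delta_{Ro} = (1 - V_I)/(1 - V_J)},
#'     \eqn{\varphi_{Ro} = \varphi_{Eo}\,\delta_{Ro}}
#'   \item specific fluxes per reaction centre:
#'     \eqn{ABS/RC = M_o / (V_J\,\varphi_{Po})},
#'     \eqn{TR_o/RC = M_o/V_J},
#'     \eqn{ET_o/RC = (M_o/V_J)\,\psi_{Eo}},
#'     \eqn{DI_o/RC = ABS/RC - TR_o/RC},
#'     \eqn{RC/ABS = \varphi_{Po}\,V_J/M_o}
#'   \item performance indices
#'     \eqn{PI_{ABS} = (RC/ABS)\cdot\frac{\varphi_{Po}}{1-\varphi_{Po}}
#'       \cdot\frac{\psi_{Eo}}{1-\psi_{Eo}}} and
#'     \eqn{PI_{total} = PI_{ABS}\cdot\frac{\delta_{Ro}}{1-\delta_{Ro}}}
#' }
#' V_J and V_I are the relative variable fluorescence values on the O-P
#' scale. All quantities are ratios of fluorescence levels, so they are
#' invariant under rescaling of the raw signal.
#'
#' When V_I <= V_J the electron-transport efficiency beyond I is undefined;
#' `delta_Ro`, `phi_Ro` and `PI_total` are returned as `NA` with a QC flag
#' rather than erroring out. Out-of-range but finite values (e.g. PI_ABS
#' above 100) are reported with a QC warning and never clamped: the
#' downstream group statistics decide what to do with them.
#'
#' @param cardinals A `cardinal_points` object.
#' @param rvf Its [relative_variable_fluorescence()]; recomputed if omitted.
#' @return An object of class `jip_parameters` (named list) with fields
#'   `Fv_over_Fm`, `M_o`, `V_J`, `V_I`, `psi_Eo`, `phi_Eo`, `delta_Ro`,
#'   `phi_Ro`, `ABS_per_RC`, `TRo_per_RC`, `ETo_per_RC`, `DIo_per_RC`,
#'   `RC_per_ABS`, `PI_ABS`, `PI_total` and `qc`.
#' @examples
#' cp <- structure(list(F_o = 5000, F_L = 6000, F_K = 8000, F_J = 12000,
#'                      F_I = 18000, F_P = 25000, qc = character()),
#'                 class = "cardinal_points")
#' jp <- jip_parameters(cp)
#' jp$Fv_over_Fm   # 0.8
#' jp$PI_ABS
#' @export
jip_parameters <- function(cardinals, rvf = relative_variable_fluorescence(cardinals)) {
  stopifnot(inherits(cardinals, "cardinal_points"))
  F_o <- cardinals$F_o; F_m <- cardinals$F_P; F_K <- cardinals$F_K
  if (!(F_m > F_o)) stop("F_m must exceed F_o")
  V_J <- rvf$V_J; V_I <- rvf$V_I
  phi_Po <- 1 - F_o / F_m
  if (V_J <= 0 || V_J >= 1 || phi_Po <= 0 || phi_Po >= 1)
    stop("index undefined (division by zero): V_J and Fv/Fm must lie strictly in (0, 1)")
  qc <- character()
  M_o <- 4 * (F_K - F_o) / (F_m - F_o)
  psi_Eo <- 1 - V_J
  phi_Eo <- phi_Po * psi_Eo
  ABS_per_RC <- M_o / (V_J * phi_Po)
  TRo_per_RC <- M_o / V_J
  ETo_per_RC <- TRo_per_RC * psi_Eo
  DIo_per_RC <- ABS_per_RC - TRo_per_RC
  RC_per_ABS <- phi_Po * V_J / M_o
  PI_ABS <- RC_per_ABS * (phi_Po / (1 - phi_Po)) * (psi_Eo / (1 - psi_Eo))
  if (V_I <= V_J) {
    qc <- c(qc, "V_I <= V_J: delta_Ro undefined, PI_total unset")
    delta_Ro <- NA_real_; phi_Ro <- NA_real_; PI_total <- NA_real_
  } else {
    delta_Ro <- (1 - V_I) / (1 - V_J)
    phi_Ro <- phi_Eo * delta_Ro
    PI_total <- if (delta_Ro < 1) PI_ABS * delta_Ro / (1 - delta_Ro) else NA_real_
  }
  if (is.finite(PI_ABS) && PI_ABS > 100)
    qc <- c(qc, "PI_ABS out of usual range (> 100)")
  structure(list(Fv_over_Fm = phi_Po, M_o = M_o, V_J = V_J, V_I = V_I,
                 psi_Eo = psi_Eo, phi_Eo = phi_Eo, delta_Ro = delta_Ro,
                 phi_Ro = phi_Ro, ABS_per_RC = ABS_per_RC,
                 TRo_per_RC = TRo_per_RC, ETo_per_RC = ETo_per_RC,
                 DIo_per_RC = DIo_per_RC, RC_per_ABS = RC_per_ABS,
                 PI_ABS = PI_ABS, PI_total = PI_total, qc = qc),
            class = "jip_parameters")
}

#' @export
print.jip_parameters <- function(x, ...) {
  cat(sprintf("<jip_parameters> Fv/Fm=%.4f V_J=%.4f PI_ABS=%.4g PI_total=%.4g\n",
              x$Fv_over_Fm, x$V_J, x$PI_ABS, x$PI_total))
  if (length(x$qc)) cat("  QC:", paste(x$qc, collapse = "; "), "\n")
  invisible(x)
}

# parameters reported per sample in the tidy fluorescence table
JIP_TABLE_PARAMS <- c("V_L", "V_K", "V_J", "Fv_over_Fm", "PI_ABS", "PI_total")

#' Per-replicate JIP-test table for a whole study
#'
#' Runs cardinal-point extraction and the JIP cascade for every sample in a
#' sample sheet and returns the tidy long-format table (one row per sample
#' and parameter) for `V_L`, `V_K`, `V_J`, `Fv/Fm`, `PI_ABS` and `PI_total`.
#' Parameters are always computed per replicate curve and summarised later;
#' curves are never averaged before extraction. Samples whose curve cannot be
#' read, or that fail QC (no variable fluorescence), are excluded with a log
#' entry on stderr.
#'
#' @param sheet A `sample_sheet` (or path to one).
#' @param config An [run_config()].
#' @return A `TreatmentTable` tibble with columns
#'   `sample_id, group, replicate, parameter, value`.
#' @export
jip_table <- function(sheet, config = run_config()) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  rows <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    s <- sheet[i, ]
    res <- tryCatch({
      tr <- read_transient(s$curve_path, sample_id = s$sample_id,
                           group = s$group, replicate = s$replicate)
      cp <- extract_cardinals(tr, config)
      if ("no variable fluorescence" %in% cp$qc)
        stop("QC failed: no variable fluorescence")
      rvf <- relative_variable_fluorescence(cp)
      jp <- jip_parameters(cp, rvf)
      vals <- c(V_L = rvf$V_L, V_K = rvf$V_K, V_J = rvf$V_J,
                Fv_over_Fm = jp$Fv_over_Fm, PI_ABS = jp$PI_ABS,
                PI_total = jp$PI_total)
      tibble::tibble(sample_id = s$sample_id, group = s$group,
                     replicate = s$replicate,
                     parameter = names(vals), value = unname(vals))
    }, error = function(e) {
      ojip_log("jip_table", paste("excluded:", conditionMessage(e)),
               sample_id = s$sample_id)
      NULL
    })
    rows[[i]] <- res
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no sample could be analysed")
  lost <- setdiff(unique(sheet$group), unique(out$group))
  if (length(lost))
    stop("all samples failed QC in group(s): ", paste(lost, collapse = ", "))
  out
}
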