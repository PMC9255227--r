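#' Chlorophyll determination coefficient sets
#'
#' Spectrophotometric coefficients converting extract absorbances at 663 and
#' 646 nm to chlorophyll a and b concentrations in micrograms per millilitre:
#' \deqn{Chl\,a = 12.25 A_{663} - 2.55 A_{646}}
#' \deqn{Chl\,b = 20.31 A_{646} - 4.91 A_{663}}
#' This is the widely used 80%-acetone set. Mixed acetone:ethanol extraction
#' media have no dedicated published set, so this one is the documented,
#' user-overridable default: supply your own named set with the same shape to
#' use different coefficients.
#'
#' @return A list with fields `name` and a 2x2 coefficient matrix `M` such
#'   that `c(chl_a, chl_b) = M %*% c(A_663, A_646)`.
#' @export
porra_coefficients <- function() {
  list(name = "porra_80pct_acetone_v1",
       M = matrix(c(12.25, -2.55,
                    -4.91, 20.31), nrow = 2, byrow = TRUE,
                  dimnames = list(c("chl_a", "chl_b"), c("A_663", "A_646"))))
}

#' Chlorophyll concentrations from extract absorbances
#'
#' Converts absorbance records to Chl a, Chl b and Chl a+b in mg per g fresh
#' mass, and the Chl a/b ratio. The extract concentration (ug/mL) from the
#' coefficient set is scaled by extract volume, dilution factor and fresh
#' mass:
#' \deqn{chl\ [mg\,g^{-1}] = C\ [\mu g\,mL^{-1}] \cdot V\ [mL] \cdot d / (1000\, m\ [g])}
#'
#' Negative computed concentrations (possible with noisy absorbances near
#' zero) are floored at 0 and flagged. Absorbances at or above 2 are outside
#' the photometric linear range and flagged. A zero Chl b leaves the a/b
#' ratio `NA` with a flag.
#'
#' @param rec A data frame (one or more rows) with columns `A_663`, `A_646`,
#'   `dilution_factor`, `fresh_mass_g`, `extract_volume_mL` and optional
#'   metadata columns (`sample_id`, `group`, `replicate`).
#' @param coefficients A coefficient set, see [porra_coefficients()].
#' @return A tibble with one row per record: metadata plus `chl_a`, `chl_b`,
#'   `chl_ab_sum` (mg/g), `chl_a_over_b` and a `qc` string (empty if clean).
#' @examples
#' pigment_concentrations(data.frame(A_663 = 0.5, A_646 = 0.2,
#'   dilution_factor = 1, fresh_mass_g = 0.1, extract_volume_mL = 10))
#' @export
pigment_concentrations <- function(rec, coefficients = porra_coefficients()) {
  rec <- as.data.frame(rec)
  need <- c("A_663", "A_646", "dilution_factor", "fresh_mass_g", "extract_volume_mL")
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols))
    stop("pigment record missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(rec$A_663 < 0 | rec$A_646 < 0)) stop("absorbances must be >= 0")
  if (any(rec$dilution_factor <= 0) || any(rec$fresh_mass_g <= 0) ||
      any(rec$extract_volume_mL <= 0))
    stop("dilution_factor, fresh_mass_g and extract_volume_mL must be positive")
  M <- coefficients$M
  out <- lapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    qc <- character()
    if (r$A_663 >= 2 || r$A_646 >= 2) qc <- c(qc, "absorbance outside linear range")
    conc_ug_ml <- as.numeric(M %*% c(r$A_663, r$A_646))   # extract, ug/mL
    if (any(conc_ug_ml < 0)) {
      qc <- c(qc, "negative concentration floored at 0")
      conc_ug_ml <- pmax(conc_ug_ml, 0)
    }
    scale <- r$extract_volume_mL * r$dilution_factor / (1000 * r$fresh_mass_g)
    chl <- conc_ug_ml * scale                              # mg / g fresh mass
    ratio <- if (chl[2] > 0) chl[1] / chl[2] else NA_real_
    if (chl[2] <= 0) qc <- c(qc, "chl_b is zero, a/b ratio unset")
    tibble::tibble(sample_id = r$sample_id %||% NA_character_,
                   group = r$group %||% NA_character_,
                   replicate = r$replicate %||% NA_integer_,
                   chl_a = chl[1], chl_b = chl[2],
                   chl_ab_sum = chl[1] + chl[2], chl_a_over_b = ratio,
                   qc = paste(qc, collapse = "; "))
  })
  dplyr::bind_rows(out)
}

#' Tidy rows from pigment records
#'
#' Long-format `TreatmentTable` rows (`Chl_a`, `Chl_b`, `Chl_ab`,
#' `Chl_a_over_b`) for the group-statistics pathway.
#'
#' @inheritParams pigment_concentrations
#' @return A tidy tibble (`sample_id, group, replicate, parameter, value`).
#' @export
pigment_table <- function(rec, coefficients = porra_coefficients()) {
  res <- pigment_concentrations(rec, coefficients)
  res |>
    dplyr::select("sample_id", "group", "replicate",
                  Chl_a = "chl_a", Chl_b = "chl_b",
                  Chl_ab = "chl_ab_sum", Chl_a_over_b = "chl_a_over_b") |>
    tidyr::pivot_longer(cols = c("Chl_a", "Chl_b", "Chl_ab", "Chl_a_over_b"),
                        names_to = "parameter", values_to = "value")
}
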