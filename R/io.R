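#' @name io_formats
#' @title On-disk formats
#' @description
#' All curve files are 2-column delimited text (`time_ms`, value) with a
#' header; the sample sheet and every tidy/summary table are delimited text
#' with a header row. The delimiter defaults to comma, with tab auto-detected
#' from the first line. Times are milliseconds everywhere; decimal points only.
#' Numbers are written with 15 significant digits so reader/writer pairs
#' round-trip exactly representable decimals bit-for-bit.
NULL

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("\t", first)) "\t" else ","
}

read_two_column <- function(path, dialect = NULL, what = "curve") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- dialect %||% detect_delim(path)
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(what, " file must have at least 2 columns: ", path)
  tt <- suppressWarnings(as.numeric(df[[1]]))
  yy <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(tt)) || any(is.na(yy)))
    stop("non-numeric values in ", what, " file: ", path)
  if (any(diff(tt) <= 0)) {
    bad <- which(diff(tt) <= 0)[1] + 1L
    stop(sprintf("non-monotone time in %s at row %d: %s", what, bad, path))
  }
  list(time_ms = tt, value = yy)
}

write_two_column <- function(time_ms, value, names, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  cat(paste(names, collapse = ","), "\n", sep = "", file = con)
  cat(sprintf("%.15g,%.15g\n", time_ms, value), sep = "", file = con)
  invisible(path)
}

#' Read a fluorescence transient from delimited text
#'
#' Expects at least two numeric columns (`time_ms`, `signal`) and at least 20
#' rows spanning the OJIP window 0.01--1000 ms. Comma or tab delimited
#' (auto-detected unless `dialect` is given).
#'
#' @param path File path.
#' @param dialect Optional delimiter override (e.g. `","` or `"\t"`).
#' @param sample_id,group,replicate Metadata; `sample_id` defaults to the
#'   file name without extension.
#' @param t_required Time span (ms) the curve must cover; the default is the
#'   O and P cardinal times.
#' @return A [fluor_transient()].
#' @export
read_transient <- function(path, dialect = NULL, sample_id = NULL,
                           group = NA_character_, replicate = NA_integer_,
                           t_required = c(0.01, 1000)) {
  tc <- read_two_column(path, dialect, "transient")
  if (length(tc$time_ms) < 20)
    stop("too few points (", length(tc$time_ms), ") in ", path)
  if (any(tc$value <= 0))
    stop("non-positive signal values in ", path)
  if (tc$time_ms[1] > t_required[1])
    stop(sprintf("time range does not cover O time (%g ms): %s", t_required[1], path))
  if (tc$time_ms[length(tc$time_ms)] < t_required[2])
    stop(sprintf("time range does not cover P time (%g ms): %s", t_required[2], path))
  fluor_transient(tc$time_ms, tc$value,
                  sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
                  group = group, replicate = replicate)
}

#' Write a fluorescence transient
#' @param x A `fluor_transient`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_transient <- function(x, path) {
  stopifnot(inherits(x, "fluor_transient"))
  write_two_column(x$time_ms, x$signal, c("time_ms", "signal"), path)
}

#' Read a modulated 820 nm reflection curve
#'
#' Same on-disk format as transients: two numeric columns, `time_ms` and the
#' relative reflection signal.
#'
#' @inheritParams read_transient
#' @return An [mr820_curve()].
#' @export
read_mr820 <- function(path, dialect = NULL, sample_id = NULL,
                       group = NA_character_, replicate = NA_integer_) {
  tc <- read_two_column(path, dialect, "MR820")
  mr820_curve(tc$time_ms, tc$value,
              sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
              group = group, replicate = replicate)
}

#' Write a modulated 820 nm reflection curve
#' @param x An `mr820_curve`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_mr820 <- function(x, path) {
  stopifnot(inherits(x, "mr820_curve"))
  write_two_column(x$time_ms, x$reflection, c("time_ms", "reflection"), path)
}

#' Read and validate a sample sheet
#'
#' The sample sheet maps each measured sample to its treatment group,
#' replicate number, transient file and (optionally) MR820 file. Required
#' columns: `sample_id`, `group`, `replicate`, `curve_path`; optional:
#' `mr820_path`. Relative paths are resolved against the sheet's directory.
#' Unknown columns are kept but trigger a warning. Groups with fewer than two
#' replicates load fine but are flagged (attribute `no_statistics`) because
#' they cannot enter ANOVA.
#'
#' @param path Path to a delimited sample sheet.
#' @param check_paths If `TRUE` (default), referenced curve files must exist.
#' @return A tibble of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path, check_paths = TRUE) {
  sep <- detect_delim(path)
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "replicate", "curve_path")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("sample sheet is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), c(required, "mr820_path"))
  if (length(extra))
    warning("ignoring unknown sample sheet column(s): ",
            paste(extra, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicated sample_id in sample sheet: ", paste(unique(dup), collapse = ", "))
  if (any(df$replicate %% 1 != 0 | df$replicate < 1))
    stop("replicate must be a positive integer")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p),
                                p, file.path(base, p))
  df$curve_path <- resolve(df$curve_path)
  if (!"mr820_path" %in% names(df)) df$mr820_path <- NA_character_
  df$mr820_path <- resolve(df$mr820_path)
  if (check_paths) {
    gone <- df$curve_path[!file.exists(df$curve_path)]
    gone <- c(gone, stats::na.omit(df$mr820_path[!is.na(df$mr820_path) &
                                                 df$mr820_path != "" &
                                                 !file.exists(df$mr820_path)]))
    if (length(gone))
      stop("referenced file(s) do not exist: ", paste(gone, collapse = ", "))
  }
  counts <- table(df$group)
  lone <- names(counts)[counts < 2]
  if (length(lone))
    ojip_log("sample_sheet", paste("group(s) with < 2 replicates, no statistics:",
                                   paste(lone, collapse = ", ")))
  out <- tibble::as_tibble(df)
  class(out) <- c("sample_sheet", class(out))
  attr(out, "no_statistics") <- lone
  out
}

#' Write a sample sheet
#' @param sheet A data frame with the sample-sheet columns.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(as.data.frame(sheet), path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write a tidy parameter table
#'
#' Long format, one row per sample and parameter, with the fixed column order
#' `sample_id, group, replicate, parameter, value`.
#'
#' @param rows A data frame with those columns (a `TreatmentTable`).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_tidy_table <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0) stop("nothing to write")
  cols <- c("sample_id", "group", "replicate", "parameter", "value")
  if (!all(cols %in% names(rows)))
    stop("tidy table needs columns: ", paste(cols, collapse = ", "))
  df <- as.data.frame(rows)[, cols]
  df$value <- sprintf("%.15g", df$value)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy parameter table
#' @param path Path written by [write_tidy_table()].
#' @return A tibble with columns `sample_id, group, replicate, parameter, value`.
#' @export
read_tidy_table <- function(path) {
  df <- read.table(path, sep = detect_delim(path), header = TRUE,
                   stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  tibble::as_tibble(df)
}

#' Read pigment absorbance records
#'
#' Delimited text with columns `sample_id, group, replicate, A_663, A_646,
#' dilution_factor, fresh_mass_g, extract_volume_mL`.
#'
#' @param path File path.
#' @return A tibble of records for [pigment_concentrations()].
#' @export
read_pigment_records <- function(path) {
  df <- read.table(path, sep = detect_delim(path), header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "replicate", "A_663", "A_646",
            "dilution_factor", "fresh_mass_g", "extract_volume_mL")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("pigment record file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tibble::as_tibble(df)
}

#' Read gas-exchange records
#'
#' Delimited text with columns `sample_id, group, replicate, Pn, Gs, Tr, Ci`
#' (net photosynthetic rate, stomatal conductance, transpiration rate and
#' intercellular CO2 concentration).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_gas_exchange <- function(path) {
  df <- read.table(path, sep = detect_delim(path), header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "replicate", "Pn", "Gs", "Tr", "Ci")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("gas-exchange file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(df[, c("Pn", "Gs", "Tr", "Ci")] < 0, na.rm = TRUE))
    warning("negative gas-exchange values present")
  tibble::as_tibble(df)
}

write_records <- function(df, path) {
  out <- as.data.frame(df)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.15g", x))
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
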