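#' Simulate a study dataset (pipeline stage 1)
#'
#' Thin orchestration wrapper around [generate_study()]: refuses to write
#' into a non-empty directory unless `force = TRUE`, and records a run
#' manifest (`manifest.json`) with the configuration snapshot, file hashes,
#' per-stage row counts, seed, timestamp and package version.
#'
#' @param dir Output dataset directory.
#' @param scenario A [scenario_spec()]; default is the flooding preset.
#' @param seed Optional seed override.
#' @param force Overwrite a non-empty directory.
#' @return Path to the written sample sheet, invisibly.
#' @export
simulate_study <- function(dir, scenario = flooding_scenario(), seed = NULL,
                           force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force)
    stop("output directory ", dir, " is not empty (use force = TRUE)")
  sheet_path <- generate_study(scenario, dir, seed = seed)
  write_manifest(dir, stage = "simulate",
                 config = list(groups = names(scenario$effects),
                               replicates = scenario$replicates,
                               control = scenario$control),
                 seed = as.integer(seed %||% scenario$seed),
                 counts = list(samples = length(scenario$effects) * scenario$replicates))
  invisible(sheet_path)
}

#' Analyse a study (pipeline stage 2)
#'
#' Runs the full per-sample analysis for every entry of a sample sheet:
#' cardinal-point extraction, relative variable fluorescence, the JIP-test
#' cascade, MR820 amplitude analysis, pigment quantification and
#' gas-exchange collection -- all per replicate -- and assembles one tidy
#' `TreatmentTable`. Normalised group-mean curves (V_O-P, V_O-J, V_O-K) and
#' their difference kinetics versus the control are computed as well.
#' Unreadable samples are skipped with a log entry; samples without an MR820
#' path produce a fluorescence-only row set with a warning.
#'
#' @param sample_sheet A `sample_sheet`, or a path to one, or a dataset
#'   directory containing `sample_sheet.csv`.
#' @param config An [run_config()].
#' @param output_dir If non-`NULL`, tidy tables and curve files are written
#'   there (`tidy_parameters.csv`, `curves_<window>.csv`,
#'   `difference_kinetics.csv`).
#' @param windows Normalisation windows to compute.
#' @param control Control group for difference kinetics.
#' @return A list with elements `tidy` (TreatmentTable), `curves` (tibble of
#'   group-mean normalised curves) and `dv` (difference kinetics).
#' @export
analyze_study <- function(sample_sheet, config = run_config(),
                          output_dir = NULL,
                          windows = c("O-P", "O-J", "O-K"),
                          control = "CK") {
  windows <- match.arg(windows, c("O-P", "O-J", "O-K"), several.ok = TRUE)
  if (is.character(sample_sheet)) {
    path <- sample_sheet
    if (dir.exists(path)) path <- file.path(path, "sample_sheet.csv")
    sample_sheet <- read_sample_sheet(path)
  }
  dataset_dir <- dirname(sample_sheet$curve_path[1])

  tidy <- jip_table(sample_sheet, config)

  # MR820 amplitude per sample (fluorescence-only run when paths missing)
  has_mr <- !is.na(sample_sheet$mr820_path) & sample_sheet$mr820_path != ""
  if (!all(has_mr))
    warning(sum(!has_mr), " sample(s) lack an MR820 path; fluorescence-only for those")
  mr_rows <- lapply(which(has_mr), function(i) {
    s <- sample_sheet[i, ]
    tryCatch({
      res <- analyze_mr820(read_mr820(s$mr820_path, sample_id = s$sample_id,
                                      group = s$group, replicate = s$replicate))
      tibble::tibble(sample_id = s$sample_id, group = s$group,
                     replicate = s$replicate,
                     parameter = c("delta_I_over_Io", "mr820_initial_slope"),
                     value = c(res$delta_I_over_Io, res$initial_slope))
    }, error = function(e) {
      ojip_log("mr820", paste("skipped:", conditionMessage(e)),
               sample_id = s$sample_id)
      NULL
    })
  })
  tidy <- dplyr::bind_rows(tidy, dplyr::bind_rows(mr_rows))

  pig_path <- file.path(dataset_dir, "pigments.csv")
  if (file.exists(pig_path))
    tidy <- dplyr::bind_rows(tidy, pigment_table(read_pigment_records(pig_path)))
  gas_path <- file.path(dataset_dir, "gas_exchange.csv")
  if (file.exists(gas_path)) {
    ge <- read_gas_exchange(gas_path) |>
      tidyr::pivot_longer(cols = c("Pn", "Gs", "Tr", "Ci"),
                          names_to = "parameter", values_to = "value")
    tidy <- dplyr::bind_rows(tidy, ge)
  }

  # group-mean normalised curves and difference kinetics vs control
  curves <- list(); dv <- list()
  for (w in windows) {
    per_group <- list()
    for (i in seq_len(nrow(sample_sheet))) {
      s <- sample_sheet[i, ]
      nc <- tryCatch({
        tr <- read_transient(s$curve_path, sample_id = s$sample_id,
                             group = s$group, replicate = s$replicate)
        normalize_curve(tr, extract_cardinals(tr, config), window = w,
                        n_per_decade = config$n_per_decade)
      }, error = function(e) NULL)
      if (!is.null(nc)) per_group[[s$group]] <- c(per_group[[s$group]], list(nc))
    }
    for (g in names(per_group)) {
      grid <- per_group[[g]][[1]]$time_ms
      vs <- vapply(per_group[[g]], function(cu)
        approx(log10(cu$time_ms), cu$V, xout = log10(grid), rule = 2,
               ties = "ordered")$y, numeric(length(grid)))
      curves[[paste(w, g)]] <- tibble::tibble(window = w, group = g,
                                              time_ms = grid,
                                              V = rowMeans(as.matrix(vs)))
    }
    if (control %in% names(per_group)) {
      for (g in setdiff(names(per_group), control)) {
        d <- difference_kinetics(per_group[[g]], per_group[[control]])
        dv[[paste(w, g)]] <- tibble::tibble(window = w, group = g,
                                            time_ms = d$time_ms, dV = d$dV)
      }
    }
  }
  out <- list(tidy = tidy,
              curves = dplyr::bind_rows(curves),
              dv = dplyr::bind_rows(dv))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_tidy_table(tidy, file.path(output_dir, "tidy_parameters.csv"))
    for (w in windows) {
      cw <- out$curves[out$curves$window == w, ]
      write_records(cw, file.path(output_dir,
                                  sprintf("curves_%s.csv", gsub("-", "", w))))
    }
    if (nrow(out$dv)) write_records(out$dv, file.path(output_dir, "difference_kinetics.csv"))
    write_manifest(output_dir, stage = "analyze",
                   config = list(fm_rule = config$fm_rule, alpha = config$alpha,
                                 windows = windows),
                   seed = config$seed,
                   counts = list(tidy_rows = nrow(tidy)),
                   inputs = sample_sheet$curve_path)
  }
  out
}

#' Compare treatment groups (pipeline stage 3)
#'
#' ANOVA + protected-LSD letters + percent change versus the control for
#' every parameter of a tidy table; optionally writes the report as
#' delimited text.
#'
#' @param tidy A `TreatmentTable` (or path to one from [write_tidy_table()]).
#' @param control Control group name.
#' @param alpha Significance level.
#' @param output_dir If non-`NULL`, writes `group_summary.csv` there.
#' @return The [group_summary()] tibble.
#' @export
compare_groups <- function(tidy, control = "CK", alpha = 0.05,
                           output_dir = NULL) {
  if (is.character(tidy)) tidy <- read_tidy_table(tidy)
  if (!control %in% tidy$group)
    stop("control group '", control, "' not present in the table")
  res <- group_summary(tidy, control = control, alpha = alpha)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_records(res, file.path(output_dir, "group_summary.csv"))
  }
  res
}

# run manifest: config snapshot, input hashes, counts, seed, version
write_manifest <- function(dir, stage, config, seed, counts, inputs = NULL) {
  man <- list(stage = stage,
              config = config,
              seed = seed,
              counts = counts,
              input_hashes = if (!is.null(inputs))
                as.list(tools::md5sum(inputs)) else NULL,
              output_hashes = local({
                fs <- setdiff(dir(dir, full.names = TRUE),
                              file.path(dir, "manifest.json"))
                fs <- fs[!dir.exists(fs)]
                h <- tools::md5sum(fs)
                names(h) <- basename(names(h))
                as.list(h)
              }),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              version = as.character(utils::packageVersion("ojipr")))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}
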