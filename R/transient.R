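#' Construct a fluorescence transient
#'
#' A fast chlorophyll-a fluorescence induction (OJIP) curve of a dark-adapted
#' leaf: a log-sampled time axis in milliseconds paired with the fluorescence
#' signal in arbitrary units, plus sample metadata.
#'
#' @param time_ms Strictly increasing positive times, milliseconds.
#' @param signal Finite positive fluorescence values, same length.
#' @param sample_id,group,replicate Sample metadata.
#' @param validate If `FALSE`, skip the structural checks (used internally for
#'   minimal curves in low-level interpolation work).
#' @return An object of class `fluor_transient`.
#' @seealso [read_transient()], [extract_cardinals()], [value_at()]
#' @export
fluor_transient <- function(time_ms, signal, sample_id = NA_character_,
                            group = NA_character_, replicate = NA_integer_,
                            validate = TRUE) {
  time_ms <- as.numeric(time_ms)
  signal <- as.numeric(signal)
  if (length(time_ms) != length(signal))
    stop("time_ms and signal must have the same length")
  if (any(diff(time_ms) <= 0)) {
    bad <- which(diff(time_ms) <= 0)[1] + 1L
    stop("time_ms must be strictly increasing (violated at row ", bad, ")")
  }
  if (validate) {
    if (length(time_ms) < 20)
      stop("a transient needs at least 20 points")
    if (any(!is.finite(signal)) || any(signal <= 0))
      stop("signal must be finite and positive")
    if (any(time_ms <= 0))
      stop("time_ms must be positive")
  }
  structure(list(time_ms = time_ms, signal = signal,
                 sample_id = as.character(sample_id),
                 group = as.character(group),
                 replicate = as.integer(replicate)),
            class = "fluor_transient")
}

#' @export
print.fluor_transient <- function(x, ...) {
  cat(sprintf("<fluor_transient> %s (group %s, rep %s): %d points, %.3g-%.4g ms, F in [%.4g, %.4g]\n",
              x$sample_id, x$group, x$replicate, length(x$time_ms),
              min(x$time_ms), max(x$time_ms), min(x$signal), max(x$signal)))
  invisible(x)
}

#' @export
as.data.frame.fluor_transient <- function(x, ...) {
  data.frame(time_ms = x$time_ms, signal = x$signal)
}

#' Interpolate a transient at an arbitrary time
#'
#' Linear interpolation in log10(time): OJIP curves are sampled log-uniformly
#' and all of their structure lives on a logarithmic time axis, so log-linear
#' interpolation keeps the relative error uniform across decades. The value is
#' exact when `t_ms` coincides with a sample time. No extrapolation is done.
#'
#' @param x A `fluor_transient` (or `mr820_curve`).
#' @param t_ms Time(s) in ms, each within the sampled range.
#' @return Interpolated signal value(s).
#' @export
value_at <- function(x, t_ms) {
  stopifnot(inherits(x, c("fluor_transient", "mr820_curve")))
  tt <- x$time_ms
  yy <- if (inherits(x, "mr820_curve")) x$reflection else x$signal
  if (any(t_ms < tt[1] | t_ms > tt[length(tt)]))
    stop(sprintf("t_ms outside sampled range [%g, %g] ms; no extrapolation",
                 tt[1], tt[length(tt)]))
  approx(log10(tt), yy, xout = log10(t_ms), ties = "ordered")$y
}

#' Apply a 3-point running median to a transient
#'
#' Optional pre-extraction denoising; off by default everywhere because the
#' cardinal-point definitions assume the recorded signal.
#'
#' @param x A `fluor_transient`.
#' @param k Odd window width.
#' @return A smoothed `fluor_transient`.
#' @export
smooth_transient <- function(x, k = 3L) {
  stopifnot(inherits(x, "fluor_transient"))
  x$signal <- as.numeric(runmed(x$signal, k, endrule = "keep"))
  x
}

#' Extract the cardinal points O, L, K, J, I, P
#'
#' Reads the fluorescence level at each configured cardinal time by
#' log-time interpolation: F_o at the O time (0.01 ms by default), F_L at
#' 0.15 ms, F_K at 0.3 ms, F_J at 2 ms, F_I at 30 ms, and F_P either at the
#' P time (1000 ms, default) or as the curve maximum, depending on
#' `config$fm_rule`. A QC flag `"no variable fluorescence"` is raised when
#' the curve barely rises (F_P < 1.05 F_o).
#'
#' @param x A `fluor_transient`.
#' @param config An [run_config()] object.
#' @return An object of class `cardinal_points`: named values `F_o`, `F_L`,
#'   `F_K`, `F_J`, `F_I`, `F_P`, the times used, and a `qc` character vector
#'   of flags (empty when clean).
#' @examples
#' tr <- generate_transient(transient_spec(noise_cv = 0), seed = 1)
#' extract_cardinals(tr)
#' @export
extract_cardinals <- function(x, config = run_config()) {
  stopifnot(inherits(x, "fluor_transient"), inherits(config, "ojip_config"))
  if (config$smooth) x <- smooth_transient(x)
  ct <- config$cardinal_times_ms
  rng <- range(x$time_ms)
  for (p in names(ct)) {
    if (ct[[p]] < rng[1] || ct[[p]] > rng[2])
      stop(sprintf("time range [%g, %g] ms does not cover %s time (%g ms)",
                   rng[1], rng[2], p, ct[[p]]))
  }
  f <- value_at(x, ct)
  names(f) <- paste0("F_", c("o", "L", "K", "J", "I", "P"))
  if (config$fm_rule == "curve_max") f[["F_P"]] <- max(x$signal)
  qc <- character()
  if (f[["F_P"]] < 1.05 * f[["F_o"]]) qc <- c(qc, "no variable fluorescence")
  structure(list(F_o = f[["F_o"]], F_L = f[["F_L"]], F_K = f[["F_K"]],
                 F_J = f[["F_J"]], F_I = f[["F_I"]], F_P = f[["F_P"]],
                 times_ms = ct, fm_rule = config$fm_rule,
                 sample_id = x$sample_id, group = x$group,
                 replicate = x$replicate, qc = qc),
            class = "cardinal_points")
}

#' @export
print.cardinal_points <- function(x, ...) {
  cat("<cardinal_points>",
      sprintf("F_o=%.4g F_L=%.4g F_K=%.4g F_J=%.4g F_I=%.4g F_P=%.4g",
              x$F_o, x$F_L, x$F_K, x$F_J, x$F_I, x$F_P), "\n")
  if (length(x$qc)) cat("  QC:", paste(x$qc, collapse = "; "), "\n")
  invisible(x)
}
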