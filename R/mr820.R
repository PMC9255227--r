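#' Construct a modulated 820 nm reflection curve
#'
#' MR820 kinetics track the redox state of P700/plastocyanin: on
#' illumination the reflection signal drops as PSI donors oxidise, then
#' partially recovers as electrons arrive from PSII. The decline amplitude
#' relative to the initial signal is the PSI activity proxy delta-I/I_o.
#'
#' @param time_ms Strictly increasing times, ms.
#' @param reflection Finite positive relative reflection values.
#' @param sample_id,group,replicate Sample metadata.
#' @return An object of class `mr820_curve`.
#' @export
mr820_curve <- function(time_ms, reflection, sample_id = NA_character_,
                        group = NA_character_, replicate = NA_integer_) {
  time_ms <- as.numeric(time_ms)
  reflection <- as.numeric(reflection)
  if (length(time_ms) != length(reflection))
    stop("time_ms and reflection must have the same length")
  if (length(time_ms) < 20) stop("an MR820 curve needs at least 20 points")
  if (any(diff(time_ms) <= 0)) stop("time_ms must be strictly increasing")
  if (any(!is.finite(reflection)) || any(reflection <= 0))
    stop("reflection must be finite and positive")
  structure(list(time_ms = time_ms, reflection = reflection,
                 sample_id = as.character(sample_id),
                 group = as.character(group),
                 replicate = as.integer(replicate)),
            class = "mr820_curve")
}

#' @export
print.mr820_curve <- function(x, ...) {
  cat(sprintf("<mr820_curve> %s: %d points, reflection in [%.4g, %.4g]\n",
              x$sample_id, length(x$time_ms), min(x$reflection), max(x$reflection)))
  invisible(x)
}

#' Analyse an MR820 curve
#'
#' Computes I_o (the maximum reflected signal), I_min (the minimum),
#' delta-I = I_o - I_min, the headline ratio delta-I/I_o, and the initial
#' slope of the decline phase (least-squares slope of reflection against time
#' from the maximum to the first local minimum, capped at 30% of the points).
#' The ratio and the slope quantify different things -- amplitude versus
#' speed of P700 oxidation -- and are reported separately, with delta-I/I_o
#' as the headline PSI statistic.
#'
#' Extremes are read off a running-median smoothed copy of the curve by
#' default: raw min/max under point noise carry an extreme-value bias that
#' would dominate near-flat curves from severely stressed leaves. Set
#' `smooth_k = 1` for raw extremes.
#'
#' Flags (`qc` field): `"no PSI signal"` for a constant curve (a valid
#' degenerate result: delta-I = 0, ratio 0, slope 0); `"atypical"` when the
#' maximum does not occur within the first 10% of the samples.
#'
#' @param curve An [mr820_curve()].
#' @param smooth_k Odd running-median window (default 5; 1 disables).
#' @param max_decline_frac Cap on the decline-segment length, as a fraction
#'   of the number of points.
#' @param atypical_frac Fraction of samples within which the maximum must
#'   occur for a typical curve.
#' @return An object of class `mr820_result` with fields `I_o`, `I_min`,
#'   `delta_I`, `delta_I_over_Io`, `initial_slope` (a.u. per ms) and `qc`.
#' @examples
#' mr <- generate_mr820(mr820_spec(noise_cv = 0), seed = 1)
#' analyze_mr820(mr)
#' @export
analyze_mr820 <- function(curve, smooth_k = 5L, max_decline_frac = 0.3,
                          atypical_frac = 0.1) {
  stopifnot(inherits(curve, "mr820_curve"))
  y <- curve$reflection
  n <- length(y)
  ys <- if (smooth_k > 1) as.numeric(runmed(y, smooth_k, endrule = "keep")) else y
  qc <- character()
  I_o <- max(ys); I_min <- min(ys)
  delta_I <- I_o - I_min
  if (delta_I <= .Machine$double.eps * I_o) {
    return(structure(list(I_o = I_o, I_min = I_min, delta_I = 0,
                          delta_I_over_Io = 0, initial_slope = 0,
                          sample_id = curve$sample_id, group = curve$group,
                          replicate = curve$replicate,
                          qc = "no PSI signal"),
                     class = "mr820_result"))
  }
  i_max <- which.max(ys)
  if (i_max > ceiling(atypical_frac * n)) qc <- c(qc, "atypical")
  # decline segment: maximum to first local minimum, capped
  i_end <- n
  for (i in seq(i_max + 1L, n - 1L)) {
    if (ys[i] <= ys[i - 1L] && ys[i] <= ys[i + 1L] &&
        (I_o - ys[i]) > 0.5 * delta_I) { i_end <- i; break }
  }
  i_end <- min(i_end, i_max + max(2L, ceiling(max_decline_frac * n)))
  seg <- seq(i_max, i_end)
  slope <- if (length(seg) >= 2)
    unname(coef(lm(y ~ t, data = data.frame(t = curve$time_ms[seg], y = y[seg])))[2])
  else 0
  structure(list(I_o = I_o, I_min = I_min, delta_I = delta_I,
                 delta_I_over_Io = delta_I / I_o, initial_slope = slope,
                 sample_id = curve$sample_id, group = curve$group,
                 replicate = curve$replicate, qc = qc),
            class = "mr820_result")
}

#' @export
print.mr820_result <- function(x, ...) {
  cat(sprintf("<mr820_result> I_o=%.4g delta_I=%.4g delta_I/I_o=%.4f slope=%.3g/ms\n",
              x$I_o, x$delta_I, x$delta_I_over_Io, x$initial_slope))
  if (length(x$qc)) cat("  QC:", paste(x$qc, collapse = "; "), "\n")
  invisible(x)
}
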