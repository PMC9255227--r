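#' Analysis run configuration
#'
#' Holds the cardinal-point times, the rule used for the P-level fluorescence
#' F_P, interpolation settings and statistical defaults used throughout a run.
#' The default cardinal times are the conventional OJIP definitions for
#' dark-adapted leaves: O at 0.01 ms, L at 0.15 ms, K at 0.3 ms, J at 2 ms,
#' I at 30 ms and P at 1000 ms.
#'
#' @param cardinal_times_ms Named numeric vector with elements `O`, `L`, `K`,
#'   `J`, `I`, `P` (milliseconds), strictly increasing in that order.
#' @param fm_rule How F_P is read: `"at_P_time"` takes the interpolated value
#'   at the configured P time; `"curve_max"` takes the curve maximum.
#' @param interpolation Interpolation scheme; only `"linear_log_time"`
#'   (linear in log10 time) is implemented.
#' @param alpha Significance level for ANOVA/LSD, in (0, 1).
#' @param seed Integer seed recorded with the run.
#' @param output_dir Directory where pipeline outputs are written.
#' @param n_per_decade Points per decade of the common log-time grid used for
#'   normalised curves and difference kinetics.
#' @param smooth If `TRUE`, apply a 3-point median filter to transients before
#'   cardinal-point extraction (off by default).
#'
#' @return An object of class `ojip_config` (a named list).
#' @examples
#' cfg <- run_config(alpha = 0.01)
#' cfg$cardinal_times_ms[["J"]]
#' @export
run_config <- function(cardinal_times_ms = c(O = 0.01, L = 0.15, K = 0.3,
                                             J = 2, I = 30, P = 1000),
                       fm_rule = c("at_P_time", "curve_max"),
                       interpolation = "linear_log_time",
                       alpha = 0.05,
                       seed = 1L,
                       output_dir = ".",
                       n_per_decade = 100L,
                       smooth = FALSE) {
  fm_rule <- match.arg(fm_rule)
  interpolation <- match.arg(interpolation, "linear_log_time")
  need <- c("O", "L", "K", "J", "I", "P")
  if (!all(need %in% names(cardinal_times_ms)))
    stop("cardinal_times_ms must name all of ", paste(need, collapse = ", "))
  ct <- as.numeric(cardinal_times_ms[need])
  names(ct) <- need
  if (any(!is.finite(ct)) || any(ct <= 0) || any(diff(ct) <= 0))
    stop("cardinal times must be positive and strictly increasing in the order O < L < K < J < I < P")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (n_per_decade < 20) stop("n_per_decade must be at least 20")
  structure(list(cardinal_times_ms = ct,
                 fm_rule = fm_rule,
                 interpolation = interpolation,
                 alpha = alpha,
                 seed = as.integer(seed),
                 output_dir = output_dir,
                 n_per_decade = as.integer(n_per_decade),
                 smooth = isTRUE(smooth)),
            class = "ojip_config")
}

#' Read a run configuration from a flat YAML file
#'
#' Every key is optional; defaults from [run_config()] fill the gaps, so an
#' empty file (or a missing `path`) yields the default configuration.
#' Cardinal times may be given either as a `cardinal_times_ms` mapping or as
#' individual keys `time_O` ... `time_P`.
#'
#' @param path Path to a YAML (or flat `key: value`) file.
#' @return An `ojip_config` object.
#' @export
read_run_config <- function(path) {
  raw <- if (missing(path) || !file.exists(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  def <- run_config()
  ct <- def$cardinal_times_ms
  if (!is.null(raw$cardinal_times_ms)) {
    got <- unlist(raw$cardinal_times_ms)
    ct[names(got)] <- as.numeric(got)
  }
  for (p in names(ct)) {
    key <- paste0("time_", p)
    if (!is.null(raw[[key]])) ct[[p]] <- as.numeric(raw[[key]])
  }
  run_config(cardinal_times_ms = ct,
             fm_rule = raw$fm_rule %||% def$fm_rule,
             alpha = raw$alpha %||% def$alpha,
             seed = raw$seed %||% def$seed,
             output_dir = raw$output_dir %||% def$output_dir,
             n_per_decade = raw$n_per_decade %||% def$n_per_decade,
             smooth = raw$smooth %||% def$smooth)
}

#' Write a run configuration to a YAML file
#'
#' @param config An `ojip_config` object.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "ojip_config"))
  out <- unclass(config)
  out$cardinal_times_ms <- as.list(config$cardinal_times_ms)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.ojip_config <- function(x, ...) {
  cat("<ojip_config>\n")
  cat("  cardinal times (ms):",
      paste(names(x$cardinal_times_ms), x$cardinal_times_ms, sep = "=", collapse = " "), "\n")
  cat("  fm_rule:", x$fm_rule, " alpha:", x$alpha, " seed:", x$seed, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
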