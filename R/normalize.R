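#' Double-normalise a transient over the O-P, O-J or O-K window
#'
#' Rescales the fluorescence between the O point and the window end point so
#' that V = 0 at O and V = 1 at the end of the window:
#' \deqn{V_{O-P}(t) = (F_t - F_o) / (F_P - F_o)}
#' and analogously with F_J (O-J window) or F_K (O-K window) in the
#' denominator. The curve is evaluated on a canonical log-spaced grid
#' (`n_per_decade` points per decade, endpoints included exactly) so that
#' curves from different samples or instruments are directly comparable and
#' group means are well defined.
#'
#' @param x A `fluor_transient`.
#' @param cardinals Its [extract_cardinals()] result.
#' @param window One of `"O-P"`, `"O-J"`, `"O-K"`.
#' @param n_per_decade Grid density of the common log-time grid.
#' @return A tibble of class `normalized_curve` with columns `time_ms`, `V`
#'   and attributes `window`, `sample_id`, `group`.
#' @export
normalize_curve <- function(x, cardinals = extract_cardinals(x),
                            window = c("O-P", "O-J", "O-K"),
                            n_per_decade = 100L) {
  window <- match.arg(window)
  stopifnot(inherits(x, "fluor_transient"), inherits(cardinals, "cardinal_points"))
  endpoint <- switch(window, "O-P" = "P", "O-J" = "J", "O-K" = "K")
  F_end <- cardinals[[paste0("F_", endpoint)]]
  F_o <- cardinals$F_o
  if (!(F_end > F_o))
    stop("non-inducing curve, normalization undefined (F_", endpoint, " <= F_o)")
  t0 <- cardinals$times_ms[["O"]]
  t1 <- cardinals$times_ms[[endpoint]]
  grid <- log_grid(t0, t1, n_per_decade)
  V <- (value_at(x, grid) - F_o) / (F_end - F_o)
  out <- tibble::tibble(time_ms = grid, V = V)
  attr(out, "window") <- window
  attr(out, "sample_id") <- x$sample_id
  attr(out, "group") <- x$group
  class(out) <- c("normalized_curve", class(out))
  out
}

# log-spaced grid with exact endpoints
log_grid <- function(t0, t1, n_per_decade) {
  n <- max(2L, ceiling(log10(t1 / t0) * n_per_decade) + 1L)
  10^seq(log10(t0), log10(t1), length.out = n)
}

#' Relative variable fluorescence at the L, K, J (and I) points
#'
#' The band-specific relative rises used to probe the PSII donor side, the
#' antenna connectivity and the acceptor side:
#' \deqn{V_L = (F_L - F_o)/(F_K - F_o)}
#' \deqn{V_K = (F_K - F_o)/(F_J - F_o)}
#' \deqn{V_J = (F_J - F_o)/(F_P - F_o)}
#' V_I = (F_I - F_o)/(F_P - F_o) is computed as well because the JIP-test
#' efficiency beyond the I step (delta_Ro, hence PI_total) needs it.
#'
#' @param cardinals A `cardinal_points` object.
#' @return A named list of class `rel_var_fluor` with elements `V_L`, `V_K`,
#'   `V_J`, `V_I`.
#' @examples
#' cp <- structure(list(F_o = 5000, F_L = 6000, F_K = 8000, F_J = 12000,
#'                      F_I = 18000, F_P = 25000, qc = character()),
#'                 class = "cardinal_points")
#' relative_variable_fluorescence(cp)
#' @export
relative_variable_fluorescence <- function(cardinals) {
  stopifnot(inherits(cardinals, "cardinal_points"))
  with(cardinals, {
    if (!(F_K > F_o)) stop("denominator <= 0 in the O-K band (F_K <= F_o)")
    if (!(F_J > F_o)) stop("denominator <= 0 in the O-J band (F_J <= F_o)")
    if (!(F_P > F_o)) stop("denominator <= 0 in the O-P band (F_P <= F_o)")
    structure(list(V_L = (F_L - F_o) / (F_K - F_o),
                   V_K = (F_K - F_o) / (F_J - F_o),
                   V_J = (F_J - F_o) / (F_P - F_o),
                   V_I = (F_I - F_o) / (F_P - F_o)),
              class = "rel_var_fluor")
  })
}

#' Difference kinetics versus a control group
#'
#' Pointwise difference of group-mean normalised curves,
#' Delta V(t) = mean treatment V(t) minus mean control V(t), on the common
#' grid of the first treatment curve. A positive Delta V peak near 0.3 ms
#' (the K band) or 0.15 ms (the L band) is the classic signature of
#' oxygen-evolving-complex damage or lost antenna connectivity.
#'
#' @param group_curves,control_curves Lists of `normalized_curve` objects
#'   sharing one window (a single curve may be passed bare).
#' @return A tibble with columns `time_ms`, `dV` and attribute `window`.
#' @export
difference_kinetics <- function(group_curves, control_curves) {
  as_list <- function(x) if (inherits(x, "normalized_curve")) list(x) else x
  group_curves <- as_list(group_curves)
  control_curves <- as_list(control_curves)
  wins <- unique(vapply(c(group_curves, control_curves),
                        function(cu) attr(cu, "window"), character(1)))
  if (length(wins) != 1)
    stop("window mismatch between curves: ", paste(wins, collapse = " vs "))
  grid <- group_curves[[1]]$time_ms
  mean_on_grid <- function(curves) {
    vs <- vapply(curves, function(cu)
      approx(log10(cu$time_ms), cu$V, xout = log10(grid), rule = 2,
             ties = "ordered")$y,
      numeric(length(grid)))
    rowMeans(as.matrix(vs))
  }
  out <- tibble::tibble(time_ms = grid,
                        dV = mean_on_grid(group_curves) - mean_on_grid(control_curves))
  attr(out, "window") <- wins
  out
}
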