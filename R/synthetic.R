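#' Specification of a synthetic OJIP transient
#'
#' The generator models the relative variable fluorescence rise as a sum of
#' Hill sigmoids,
#' \deqn{V(t) = \sum_i A_i\,[S(t;\tau_i,h) - S(t_O;\tau_i,h)], \quad
#'       S(t;\tau,h) = t^h/(t^h+\tau^h),}
#' with the amplitudes solved from a linear system so that the noise-free
#' curve passes exactly through the requested relative variable fluorescence
#' targets (O-P scale) at the K, J and I times (0.3, 2, 30 ms), is 0 at the
#' O time and 1 at the P time (1000 ms). One component per constrained rise
#' phase keeps the system well conditioned: four components for the three
#' targets, five when an L-point target (0.15 ms) is also requested.
#' The raw signal is then
#' \deqn{F(t) = F_o + (F_m - F_o) V(t)}
#' with multiplicative Gaussian noise of standard deviation
#' `noise_cv * F(t)` applied pointwise on a log-uniform time grid.
#'
#' @param Fo,Fm Minimal and maximal fluorescence (a.u.), `Fm > Fo > 0`.
#' @param V_K_target,V_J_target,V_I_target Relative variable fluorescence on
#'   the O-P scale at 0.3, 2 and 30 ms; each in (0, 1), strictly increasing.
#' @param V_L_target Optional O-P-scale target at 0.15 ms (below
#'   `V_K_target`); when given, a fifth Hill component pins the L band.
#' @param component_half_times_ms Half-times of the Hill components; defaults
#'   depend on the number of targets (see Details).
#' @param hill_exponent Hill exponent `h`; defaults to 2 for the 3-target
#'   basis and 2.8 for the 4-target (L-band) basis.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_points_per_decade Sampling density (>= 20).
#' @param t_range_ms Time range, default 0.01 to 1000 ms.
#' @return An object of class `transient_spec`.
#' @export
transient_spec <- function(Fo = 5000, Fm = 25000,
                           V_K_target = 0.15, V_J_target = 0.35,
                           V_I_target = 0.65, V_L_target = NULL,
                           component_half_times_ms = NULL,
                           hill_exponent = NULL,
                           noise_cv = 0.02,
                           n_points_per_decade = 100L,
                           t_range_ms = c(0.01, 1000)) {
  if (!(Fo > 0 && Fm > Fo)) stop("need Fm > Fo > 0")
  targets <- c(V_K_target, V_J_target, V_I_target)
  if (any(targets <= 0) || any(targets >= 1) || any(diff(targets) <= 0))
    stop("targets must lie in (0, 1) with V_K_target < V_J_target < V_I_target")
  if (!is.null(V_L_target)) {
    if (V_L_target <= 0 || V_L_target >= V_K_target)
      stop("V_L_target must lie in (0, V_K_target)")
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (n_points_per_decade < 20) stop("n_points_per_decade must be >= 20")
  n_comp <- if (is.null(V_L_target)) 4L else 5L
  h <- hill_exponent %||% if (n_comp == 4L) 2 else 2.8
  taus <- component_half_times_ms %||%
    if (n_comp == 4L) c(0.2, sqrt(0.3 * 2), sqrt(2 * 30), sqrt(30 * 1000))
    else c(0.11, 0.25, 1, 9, 160)
  if (length(taus) != n_comp)
    stop("component_half_times_ms must have ", n_comp, " values for this target set")
  if (any(taus <= 0) || h <= 0) stop("half-times and hill_exponent must be positive")
  structure(list(Fo = Fo, Fm = Fm,
                 V_L_target = V_L_target, V_K_target = V_K_target,
                 V_J_target = V_J_target, V_I_target = V_I_target,
                 component_half_times_ms = taus, hill_exponent = h,
                 noise_cv = noise_cv,
                 n_points_per_decade = as.integer(n_points_per_decade),
                 t_range_ms = t_range_ms),
            class = "transient_spec")
}

hill_s <- function(t, tau, h) t^h / (t^h + tau^h)

# amplitudes of the Hill components; constraints: V(t_O)=0 (by construction),
# V at each target time = target, V(t_P)=1
solve_hill_amplitudes <- function(spec) {
  t0 <- spec$t_range_ms[1]; tP <- spec$t_range_ms[2]
  times <- c(if (!is.null(spec$V_L_target)) 0.15, 0.3, 2, 30, tP)
  v <- c(spec$V_L_target, spec$V_K_target, spec$V_J_target, spec$V_I_target, 1)
  taus <- spec$component_half_times_ms; h <- spec$hill_exponent
  M <- outer(times, taus, function(t, tau) hill_s(t, tau, h) - hill_s(t0, tau, h))
  A <- tryCatch(solve(M, v),
                error = function(e) stop("degenerate half-times: amplitude system is singular"))
  list(A = A, times = times, targets = v)
}

# noise-free V(t) for a spec
hill_v <- function(spec, t, amplitudes = solve_hill_amplitudes(spec)$A) {
  t0 <- spec$t_range_ms[1]
  taus <- spec$component_half_times_ms; h <- spec$hill_exponent
  as.numeric(colSums(amplitudes * (outer(taus, t, function(tau, tt) hill_s(tt, tau, h)) -
                                     hill_s(t0, taus, h))))
}

#' Generate a synthetic OJIP transient
#'
#' Builds the noise-free Hill-component curve of a [transient_spec()] on a
#' log-uniform grid, applies seeded multiplicative Gaussian noise, and
#' returns a [fluor_transient()]. Identical spec and seed give bit-identical
#' curves. Target combinations whose solved curve dips more than 0.02 below
#' the O level or above the P level are rejected as unreachable; milder
#' negative amplitudes (flat target combinations) are tolerated and recorded
#' in the `solver` attribute.
#'
#' @param spec A [transient_spec()].
#' @param seed Integer seed for the noise.
#' @param sample_id,group,replicate Metadata for the resulting transient.
#' @return A `fluor_transient` with attributes `ground_truth` (the noise-free
#'   targets) and `solver` (amplitudes).
#' @examples
#' tr <- generate_transient(transient_spec(noise_cv = 0), seed = 1)
#' range(tr$signal)
#' @export
generate_transient <- function(spec, seed, sample_id = NA_character_,
                               group = NA_character_, replicate = NA_integer_) {
  stopifnot(inherits(spec, "transient_spec"))
  sol <- solve_hill_amplitudes(spec)
  grid <- log_grid(spec$t_range_ms[1], spec$t_range_ms[2], spec$n_points_per_decade)
  V <- hill_v(spec, grid, sol$A)
  if (min(V) < -0.02 || max(V) > 1.02)
    stop("unreachable target combination: solved curve leaves [0, 1] by more than 0.02")
  F_clean <- spec$Fo + (spec$Fm - spec$Fo) * V
  if (spec$noise_cv > 0) {
    set.seed(as.integer(seed))
    F_noisy <- F_clean * (1 + spec$noise_cv * rnorm(length(F_clean)))
    F_noisy <- pmax(F_noisy, .Machine$double.eps * spec$Fo)
  } else {
    F_noisy <- F_clean
  }
  out <- fluor_transient(grid, F_noisy, sample_id = sample_id, group = group,
                         replicate = replicate)
  attr(out, "ground_truth") <- list(V_L = spec$V_L_target, V_K = spec$V_K_target,
                                    V_J = spec$V_J_target, V_I = spec$V_I_target,
                                    Fo = spec$Fo, Fm = spec$Fm)
  attr(out, "solver") <- list(amplitudes = sol$A, dip = min(V))
  out
}

#' Specification of a synthetic MR820 curve
#'
#' Oxidation/re-reduction model for the modulated 820 nm reflection signal:
#' \deqn{MR(t) = I_o - \Delta I\,[(1 - e^{-t/\tau_{ox}}) -
#'   r\,(1 - e^{-t/\tau_{red}})] + \epsilon}
#' The curve starts at I_o, declines as P700/PC oxidise with time constant
#' `tau_ox_ms`, and partially recovers (fraction `r`) as PSII electrons
#' arrive with the slower constant `tau_red_ms`.
#'
#' @param Io Initial (maximum) reflection, a.u.
#' @param delta_I Decline amplitude parameter, in `[0, Io)`.
#' @param tau_ox_ms Oxidation time constant (ms).
#' @param tau_red_ms Re-reduction time constant, `> tau_ox_ms`.
#' @param recovery_fraction Recovered fraction `r` in `[0, 1)`.
#' @param noise_cv Multiplicative noise CV. Modulated-reflection signals are
#'   lock-in averaged, so the default point noise (0.002) is an order of
#'   magnitude below the fluorescence default.
#' @param n_points_per_decade,t_range_ms Sampling grid.
#' @return An object of class `mr820_spec`.
#' @export
mr820_spec <- function(Io = 1, delta_I = 0.3, tau_ox_ms = 1, tau_red_ms = 60,
                       recovery_fraction = 0.35, noise_cv = 0.002,
                       n_points_per_decade = 100L, t_range_ms = c(0.01, 1000)) {
  if (Io <= 0) stop("Io must be positive")
  if (delta_I < 0 || delta_I >= Io) stop("delta_I must lie in [0, Io)")
  if (recovery_fraction < 0 || recovery_fraction >= 1)
    stop("recovery_fraction must lie in [0, 1)")
  if (tau_ox_ms <= 0 || tau_red_ms <= tau_ox_ms)
    stop("need tau_red_ms > tau_ox_ms > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(Io = Io, delta_I = delta_I, tau_ox_ms = tau_ox_ms,
                 tau_red_ms = tau_red_ms, recovery_fraction = recovery_fraction,
                 noise_cv = noise_cv,
                 n_points_per_decade = as.integer(n_points_per_decade),
                 t_range_ms = t_range_ms),
            class = "mr820_spec")
}

mr820_model <- function(spec, t) {
  spec$Io - spec$delta_I * ((1 - exp(-t / spec$tau_ox_ms)) -
    spec$recovery_fraction * (1 - exp(-t / spec$tau_red_ms)))
}

#' Noise-free delta-I/I_o implied by an MR820 spec
#'
#' The ratio [analyze_mr820()] would report for the noise-free model curve on
#' its grid: (max - min)/max. Used as scenario ground truth.
#'
#' @param spec An [mr820_spec()].
#' @return A single number in `[0, 1)`.
#' @export
mr820_true_ratio <- function(spec) {
  grid <- log_grid(spec$t_range_ms[1], spec$t_range_ms[2], spec$n_points_per_decade)
  y <- mr820_model(spec, grid)
  (max(y) - min(y)) / max(y)
}

#' Generate a synthetic MR820 curve
#'
#' @param spec An [mr820_spec()].
#' @param seed Integer seed for the noise.
#' @param sample_id,group,replicate Metadata.
#' @return An [mr820_curve()].
#' @export
generate_mr820 <- function(spec, seed, sample_id = NA_character_,
                           group = NA_character_, replicate = NA_integer_) {
  stopifnot(inherits(spec, "mr820_spec"))
  grid <- log_grid(spec$t_range_ms[1], spec$t_range_ms[2], spec$n_points_per_decade)
  y <- mr820_model(spec, grid)
  if (spec$noise_cv > 0) {
    set.seed(as.integer(seed))
    y <- y * (1 + spec$noise_cv * rnorm(length(y)))
    y <- pmax(y, .Machine$double.eps * spec$Io)
  }
  mr820_curve(grid, y, sample_id = sample_id, group = group,
              replicate = replicate)
}
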