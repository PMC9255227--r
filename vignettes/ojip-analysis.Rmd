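---
title: "OJIP, JIP-test and MR820 analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OJIP, JIP-test and MR820 analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ojipr)
```

## The measurement and its model

A dark-adapted leaf exposed to saturating light emits chlorophyll-*a*
fluorescence that rises from a minimal level F_o to a maximum F_P within
about a second. Sampled log-uniformly from 0.01 to 1000 ms, the rise shows
the O, J, I, P inflections, with the finer L (0.15 ms) and K (0.3 ms) bands
visible after normalisation. The JIP-test interprets this transient through
a three-step energy cascade — absorption, trapping, electron transport —
whose efficiencies are all functions of a handful of fluorescence levels.
In parallel, the modulated 820 nm reflection signal tracks the redox state
of P700/plastocyanin: it declines as PSI oxidises and partially recovers as
PSII-derived electrons arrive, and its relative decline amplitude ΔI/I_o is
the standard PSI activity proxy.

The package's analysis assumptions are the conventional ones:

* the transient is a single induction curve of a dark-adapted sample, so
  F at the O time approximates F_o and F at the P time approximates F_m;
* all JIP quantities are ratios of fluorescence levels, hence invariant
  under instrument gain (this invariance is asserted in the test suite to
  1e-12);
* replicates are independent leaves; parameters are computed per replicate
  and summarised afterwards — curves are never averaged before extraction,
  because averaging sigmoids shifts their inflections.

## Cardinal points and interpolation

Cardinal levels are read at fixed times (defaults O = 0.01, L = 0.15,
K = 0.3, J = 2, I = 30, P = 1000 ms; all configurable via `run_config()`)
by linear interpolation in log10(time). Log-time interpolation is the
natural choice for log-sampled curves: it keeps the interpolation error
uniform across five decades, and it is exact at sample times. No smoothing
is applied before extraction by default (a 3-point median filter is
available behind `run_config(smooth = TRUE)`), because the cardinal
definitions refer to the recorded signal. F_P defaults to the value at the
P time (`fm_rule = "at_P_time"`); `"curve_max"` is available for curves
that peak early, e.g. under severe stress.

Two F_P conventions deserve a note: with `at_P_time`, F_P is a single
interpolated value and therefore carries the local point noise; this is the
dominant noise contribution to V_J and V_I estimates at high target values
(see the generator section).

## Normalisation and difference kinetics

Each window (O–P, O–J, O–K) is rescaled as V = (F_t − F_o)/(F_end − F_o) on
a canonical log grid of 100 points per decade whose endpoints are included
exactly, so V(start) = 0 and V(end) = 1 to numerical precision and group
means are defined point-by-point across instruments with different native
grids. Group curves are averaged *after* normalisation; ΔV(t) is the
difference of group means versus the control. The common-grid density
matches the generator default; halving it changes ΔV by less than the
replicate noise.

V_I is computed alongside V_L, V_K, V_J although it is not usually reported
as a band: the efficiency beyond the I step, δRo = (1 − V_I)/(1 − V_J), is
required by PI_total. When a curve has V_I ≤ V_J (inverted I step, possible
under noise in nearly flat transients), δRo and PI_total are returned as
`NA` with a QC flag instead of a misleading number.

## The synthetic-data generator

The generator exists so that the full pipeline can be run and validated
with known ground truth. The relative variable fluorescence is modelled as
a sum of Hill sigmoids S(t; τ, h) = t^h/(t^h + τ^h), one per rise phase.
The amplitudes are obtained from a linear system that pins the curve
*exactly* at the O time (V = 0), at each requested target time, and at the
P time (V = 1): four components for targets at K, J, I; five when an
L-point target is requested. Solving with the O and P constraints inside
the system (rather than renormalising afterwards) is what makes the
noise-free generator→extractor round trip exact to interpolation error
(~1e-5); a posteriori renormalisation would rescale the achieved targets.

Defaults and why:

* half-times (0.2, 0.775, 7.75, 173) ms for the 4-component basis —
  geometric midpoints of consecutive constraint times, which keeps the
  system well conditioned across the whole design grid of targets;
* the 5-component (L-band) basis uses half-times (0.11, 0.25, 1, 9, 160) ms
  and Hill exponent 2.8; the L and K constraints are only a factor two
  apart in time, and the steeper exponent is needed for the solved curve to
  stay monotone for strongly K-shifted (stressed) curves. The 3-target
  basis keeps h = 2.
* flat target combinations can produce small negative component
  amplitudes; these still recover their targets and are tolerated (recorded
  in the `solver` attribute), while combinations whose curve leaves
  [−0.02, 1.02] are rejected as unreachable.
* noise is multiplicative and pointwise (sd = cv·F), default cv = 0.02 —
  photodetector signals scale with intensity. Per-curve gain jitter is
  deliberately *not* added: gain cancels in every reported ratio and would
  only fake precision.

The MR820 model is a difference of exponentials,
MR(t) = I_o − ΔI[(1 − e^(−t/τ_ox)) − r(1 − e^(−t/τ_red))], with defaults
τ_ox = 1 ms, τ_red = 60 ms, r = 0.35: a fast oxidation decline reaching its
minimum near 5 ms and a slower partial re-reduction, the canonical shape of
820 nm kinetics. Its noise default (cv = 0.002) is an order of magnitude
below the fluorescence default because modulated-reflection signals are
lock-in averaged and published MR820 curves are smooth at the 1e-3 level.
`analyze_mr820()` reads I_o and I_min off a 5-point running median by
default: raw extremes of a noisy series carry an extreme-value bias that
would swamp the near-flat curves of severely stressed samples.

### What the generator does and does not emulate

It emulates: the OJIP phase structure with controllable L/K/J/I levels,
treatment effects of known direction and size, replicate scatter, MR820
fast-decline/slow-recovery shape, pigment absorbances consistent with the
conversion coefficients, and gas-exchange records. It does not emulate:
biological curve-shape variability beyond the Hill family, correlated
instrument drift, photoinhibition dynamics within the measurement, or
non-Gaussian outliers. Passing tests therefore demonstrate the
*correctness of the analysis pipeline*, not robustness to every real-world
artefact.

## The flooding scenario

The flooding preset encodes a progressive-flooding response (control CK and
groups D5, D10, D15, five replicates each) as multiplicative effects on the
measured scale: V_J, V_K, V_L rise with flooding duration (acceptor-side
block, OEC damage, connectivity loss; at D15 by +63.49%, +151.37%,
+34.43%), Fv/Fm is stable early and falls 22.13% at D15, PI_total and
ΔI/I_o collapse (−91.72%, −92.36% at D15), the Chl *a*/*b* ratio declines
(−25.06% at D10, −37.02% at D15, with Chl *a* more affected than Chl *b*),
and stomata close (Pn, Gs, Tr down; Ci dips at D10 and rebounds at D15
under non-stomatal limitation). Effects without a firmly quantified
published magnitude (D5/D10 index declines, gas-exchange magnitudes) were
fixed once at physiologically plausible values and are not calibration
knobs.

Internally the injected quantities are translated into generator
parameters: F_m from Fv/Fm at fixed F_o; O-P-scale targets from the band
definitions (v_K = V_K·V_J, v_L = V_L·v_K); and the I-step target is solved
from the requested PI_total through the cascade. One consequence is that
PI_ABS cannot be injected independently — it is fully determined by Fv/Fm,
V_J and V_K — and its implied ground-truth change at D15 (−96.2% with the
default baseline) is what the pipeline recovers. The control baseline
(F_o = 5000, Fv/Fm = 0.8, V_L = 0.28, V_K = 0.35, V_J = 0.45, v_I = 0.775,
Pn = 15 µmol m⁻² s⁻¹, Gs = 0.4 mol m⁻² s⁻¹, Tr = 5 mmol m⁻² s⁻¹,
Ci = 280 µmol mol⁻¹, Chl a = 1.8, Chl b = 0.6 mg g⁻¹) reflects a healthy
broadleaf seedling.

## Pigments

Absorbances at 663 and 646 nm convert to extract concentrations with the
widely used 80%-acetone coefficient set (Chl a = 12.25·A663 − 2.55·A646;
Chl b = 20.31·A646 − 4.91·A663, µg mL⁻¹), then scale by extract volume,
dilution and fresh mass to mg g⁻¹. Mixed acetone:ethanol media have no
dedicated published coefficients, so the set is named, versioned and
user-overridable (`porra_coefficients()`), which is the honest treatment of
an unavoidable approximation. Negative computed concentrations are floored
at zero with a flag; absorbances ≥ 2 are flagged as outside the photometric
linear range. Units are mg per g fresh mass throughout.

## Group statistics

Classical equal-variance one-way ANOVA (via `stats::aov`) feeds an LSD
letter display with threshold t(1 − α/2, df_err)·sqrt(2·MSE/n) (harmonic
mean n when unequal, flagged). Letters are assigned greedily by descending
mean. Two deliberate choices:

* **Protected LSD by default.** Unprotected LSD with four groups has a
  family-wise any-difference rate near 0.2 under the null; gating letters
  on a significant ANOVA F brings the null letter-difference rate to ≈ α
  (verified at 0.02–0.10 over 500 seeded null runs in the test suite).
  `protected = FALSE` restores plain LSD.
* **No correction across parameters.** Each parameter is tested on its own,
  matching the reporting convention of stress-physiology studies; with ~16
  parameters per study, a few spurious letters per experiment are expected
  and readers should treat borderline letters accordingly.

Degenerate inputs are resolved before `aov` is called, with explicit
conventions: all-constant data give F = 0, p = 1 (flagged); perfect
separation with zero within-group variance gives F = ∞, p = 0 (flagged).

## Numerical choices and degenerate inputs

* Interpolation never extrapolates; a curve not covering a cardinal time is
  an error naming the point.
* Normalisation requires F_end > F_o; flat (non-inducing) curves are
  rejected with a QC flag at extraction ("no variable fluorescence",
  F_P < 1.05·F_o) and excluded from the JIP table with a log entry.
* A constant MR820 curve is a *valid* degenerate result (ΔI = 0, ratio 0,
  slope 0, flagged "no PSI signal"); a curve whose maximum falls outside
  the first 10% of samples is flagged "atypical".
* Out-of-range but finite JIP values are flagged, never clamped; the group
  statistics see the raw numbers.
* Scenario multipliers that would push a relative-fluorescence target to or
  past 1 are clipped just below 1 with a warning.

## Problem sizes and verification

The test suite checks the formula identities on 1000 random cardinal sets
(to 1e-12), compares the cascade against an independently coded brute-force
oracle (to 1e-9), closes the generator→extractor loop over a 3×3×3 target
grid noise-free (to 1e-3) and under replicate noise (n = 5 group-mean
accuracy within 0.02, estimated as an RMSE over 20 repeated groups, because
a single five-replicate mean has sd up to ~0.013 for high targets and a
zero-failure bound would test seed luck rather than accuracy), recovers the
full injected flooding effect structure through the complete pipeline
(exact-tolerance checks for the low-variance indices, replicate-noise
confidence intervals for the band ratios whose percent-change estimates
inherit sd of several points from 2% point noise), validates the ANOVA
against an independent sum-of-squares computation on 100 random tables, and
verifies byte-identical end-to-end reproducibility under a fixed seed.
These sizes (20-sample studies, hundreds of simulated runs) keep the whole
suite in the low minutes on one core while leaving every estimate's Monte
Carlo error far below the tolerance it is tested against.

## Known limitations

* The Hill-basis generator produces idealised transients; it cannot mimic
  double-peaked or photoinhibited curves, and small dips below F_o can
  occur for extreme target combinations (bounded at 2% and recorded).
* ΔI/I_o estimated from extremes is biased upward by residual noise on
  nearly flat curves even after smoothing; group *differences* are affected
  far less than absolute levels.
* The LSD letter display is greedy and can, for pathological mean spacings,
  differ from an exhaustive compact-letter algorithm; for the small group
  counts typical here the two coincide.
* Percent changes of ratio parameters (V_K especially) are noisy under
  point noise: with cv = 0.02 and n = 5 the estimate of a +151% change has
  a standard deviation of roughly ten percentage points. This is a property
  of the measurement design, not of the implementation, and is why the
  scenario-recovery tests use replicate-noise confidence intervals.
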