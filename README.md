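# ojipr

Analysis of fast chlorophyll-*a* fluorescence induction (OJIP) transients,
JIP-test performance indices and modulated 820 nm reflection (MR820)
kinetics, for plant-stress phenotyping. The package targets the standard
workflow of flooding/drought/heat studies on leaves: dark-adapted OJIP and
MR820 curves measured per replicate, pigment extracts and gas-exchange
records per plant, and treatment groups compared by one-way ANOVA with an
LSD letter display and percent change versus the control. A seeded
synthetic-data generator produces complete studies with known ground truth,
so every step of the pipeline can be exercised and validated without
instrument files.

## What it computes

From each transient, the cardinal fluorescence levels are read by
interpolation on a logarithmic time axis at the conventional times — O
(0.01 ms), L (0.15 ms), K (0.3 ms), J (2 ms), I (30 ms), P (1000 ms) — and
three double normalisations are formed:

    V_O-P(t) = (F_t − F_o) / (F_P − F_o)
    V_O-J(t) = (F_t − F_o) / (F_J − F_o)
    V_O-K(t) = (F_t − F_o) / (F_K − F_o)

with the band-specific relative variable fluorescence values

    V_L = (F_L − F_o)/(F_K − F_o)   (antenna connectivity, L band)
    V_K = (F_K − F_o)/(F_J − F_o)   (OEC / donor side, K band)
    V_J = (F_J − F_o)/(F_P − F_o)   (acceptor side, J step)

and difference kinetics ΔV(t) against the control group. The JIP-test
cascade follows Strasser's energy-flux framework:

    φPo = Fv/Fm = 1 − F_o/F_m            M_o  = 4(F_K − F_o)/(F_m − F_o)
    ψEo = 1 − V_J                        δRo  = (1 − V_I)/(1 − V_J)
    ABS/RC = M_o/(V_J φPo)               TR_o/RC = M_o/V_J
    ET_o/RC = (M_o/V_J) ψEo              DI_o/RC = ABS/RC − TR_o/RC
    PI_ABS  = (φPo V_J/M_o) · φPo/(1−φPo) · ψEo/(1−ψEo)
    PI_total = PI_ABS · δRo/(1−δRo)

MR820 curves yield I_o (maximum reflection), ΔI = I_o − I_min, the PSI
activity proxy ΔI/I_o, and the initial decline slope. Pigment absorbances
convert to Chl *a*, Chl *b*, Chl *a*+*b* (mg g⁻¹ fresh mass) and the
Chl *a*/*b* ratio. Every parameter is computed per replicate and compared
across groups with classical one-way ANOVA, Fisher-protected LSD compact
letters, and percent change versus the control.

## Worked example

```r
library(ojipr)

# one noise-free synthetic transient and its JIP parameters
cp <- extract_cardinals(generate_transient(transient_spec(noise_cv = 0), seed = 1))
jip_parameters(cp)
#> <jip_parameters> Fv/Fm=0.8000 V_J=0.3500 PI_ABS=3.467 PI_total=4.044

# a full four-group flooding study: simulate, analyse, compare
d <- tempfile("flood")
simulate_study(d, flooding_scenario(seed = 1))
res <- analyze_study(d)
gs  <- compare_groups(res$tidy)
subset(gs, parameter %in% c("PI_ABS", "Fv_over_Fm"))
#>    parameter group n  mean      sd letter   F        p percent_change
#> 1 Fv_over_Fm    CK 5 0.802 0.00262      a 469 8.53e-16          0.000
#> 2 Fv_over_Fm    D5 5 0.800 0.00652      a 469 8.53e-16         -0.287
#> 3 Fv_over_Fm   D10 5 0.775 0.00570      b 469 8.53e-16         -3.334
#> 4 Fv_over_Fm   D15 5 0.630 0.01434      c 469 8.53e-16        -21.462
#> 5     PI_ABS    CK 5 2.811 0.15322      a 585 1.48e-16          0.000
#> 6     PI_ABS    D5 5 1.640 0.14676      b 585 1.48e-16        -41.678
#> 7     PI_ABS   D10 5 0.559 0.06741      c 585 1.48e-16        -80.120
#> 8     PI_ABS   D15 5 0.111 0.01219      d 585 1.48e-16        -96.038
```

Reading the report: groups sharing a `letter` are not significantly
different at α = 0.05 (protected LSD); `percent_change` is signed relative
to CK. The example shows the classic stress signature — the performance
index PI_ABS collapses by ~96% after 15 days of simulated flooding while
Fv/Fm, the least sensitive index, falls by only ~21%.

A subcommand CLI wrapping the same three stages is installed at
`exec/ojip` (`ojip simulate | analyze | compare`).

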