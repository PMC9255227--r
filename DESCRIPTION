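Package: ojipr
Title: OJIP Chlorophyll Fluorescence Transients, JIP-Test Indices and
    Modulated 820 nm Reflection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fast chlorophyll-a fluorescence induction
    (OJIP) transients and modulated 820 nm reflection (MR820) kinetics from
    dark-adapted leaves, as used in plant stress phenotyping. Extracts the
    O, L, K, J, I and P cardinal points by interpolation on a logarithmic
    time axis, computes the double-normalised curves and the relative
    variable fluorescence values V_L, V_K and V_J, derives the JIP-test
    parameter cascade (Fv/Fm, quantum yields, specific energy fluxes,
    PI_ABS and PI_total), quantifies MR820 decline amplitude (delta-I/I_o)
    as a PSI activity proxy, converts extract absorbances to chlorophyll
    concentrations, and compares treatment groups with one-way ANOVA,
    protected-LSD letter displays and percent change versus control. A
    seeded synthetic-data generator produces complete study datasets
    (transients, MR820 curves, pigment and gas-exchange records) with known
    ground truth so the whole pipeline can be exercised and validated
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
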