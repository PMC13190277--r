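Package: aisephys
Title: Axon Initial Segment Morphometry and Intrinsic Excitability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for quantifying axon-initial-segment (AIS)
    structure and intrinsic neuronal excitability from current-clamp
    recordings and fluorescence line profiles. Extracts action-potential
    threshold (10 V/s dV/dt criterion), amplitude and half-width; computes
    resting membrane potential, input resistance, membrane time constant,
    capacitance and rheobase from step protocols; measures AIS length and
    soma distance with the 0.33-of-maximum fluorescence rule; estimates
    lesion volumes from serial sections; and compares experimental groups
    with bootstrap estimation statistics and Bayesian hierarchical factorial
    models with animal-level random effects, estimated marginal means and
    directional evidence ratios. A synthetic-data module generates passive
    and spiking sweeps, trapezoidal AIS profiles, lesion series and
    hierarchical cohorts with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    coda,
    rjags,
    minpack.lm,
    tibble,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    emmeans,
    optparse
Config/testthat/edition: 3
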