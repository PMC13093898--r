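Package: clampr
Title: Patch-Clamp Intrinsic Excitability and Spontaneous EPSC Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feature extraction and group comparison for whole-cell
    patch-clamp recordings of cortical pyramidal neurons. Extracts active
    intrinsic-excitability features (dV/dt-based spike threshold, waveform
    kinetics, f-I curve gain, rheobase and latency) from current-clamp step
    protocols, passive membrane properties (input resistance, membrane time
    constant, input capacitance, sag ratio) from hyperpolarizing steps, and
    spontaneous excitatory postsynaptic currents from 30-s voltage-clamp
    sweeps via threshold-based detection on a curved baseline with
    automated noise rejection and test-pulse series-resistance monitoring.
    Includes cell-level quality-control gates, a three-arm statistical
    comparison layer (Kruskal-Wallis with post hoc contrasts, permutation
    tests on f-I curves), and a seeded synthetic-cohort generator with
    known ground truth so that every stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
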