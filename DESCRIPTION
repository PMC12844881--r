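Package: thermofate
Title: Thermal-Fate Analysis of Cortical Neuron Activity at Fever-Range
    Temperatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intracellular and extracellular cortical
    recordings collected while temperature is raised from 30 to 36 and 39
    degrees Celsius (fever range), together with body-temperature telemetry.
    Extracts current-clamp trace features (resting membrane potential, spike
    threshold by a second-derivative criterion, evoked post-synaptic potential
    peak and late component, input resistance, rheobase, F-I curves), assigns
    thermal fates to neurons (NEVER/STOP/STAY/START), classifies extracellular
    units into narrow- and wide-spiking classes via trough-to-peak duration
    with a Hartigan dip test of bimodality and one-dimensional 2-means, and
    computes period-restricted normalized firing rates and fever-episode
    metrics from telemetry. A synthetic-data generator reproduces the
    temperature-dependent statistical structure of such experiments so that
    every stage of the pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
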