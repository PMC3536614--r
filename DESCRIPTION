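Package: sorn
Title: Self-Organizing Recurrent Network Simulation and Synaptic Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a self-organizing recurrent network (SORN) of binary
    threshold neurons in which additive spike-timing-dependent plasticity,
    synaptic normalization, intrinsic plasticity, inhibitory STDP and
    structural plasticity interact. Provides the full analysis suite for the
    emergent statistics of such networks: inter-spike-interval and
    coefficient-of-variation summaries, log-binned synaptic weight histograms
    with lognormal fits, connectivity phase classification, synapse lifetime
    power-law estimation, weight-fluctuation statistics, rich-get-richer STDP
    curves, and a Gibrat proportionate-growth null model with and without
    multiplicative normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
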