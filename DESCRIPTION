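Package: cableEF
Title: Compartmental Cable Models of Neurons in Uniform Extracellular Electric Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds branched multi-compartment cable models of neurons
    (parametric CA1-pyramidal-like artificial cells, SWC reconstructions, and
    seeded synthetic dendritic trees with controlled asymmetry), couples them
    to a uniform extracellular electric field through per-compartment
    extracellular potentials, and integrates Hodgkin-Huxley-type membrane
    dynamics with a backward-Euler tree solver. Protocols compute electric
    field firing thresholds by bisection, firing rate versus field curves,
    morphology-parameter threshold sweeps, synaptic co-stimulation effects,
    action potential initiation diagnostics, and subthreshold membrane
    polarization profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
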