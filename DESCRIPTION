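Package: dendroclust
Title: Simulation of Activity-Dependent Synaptic Organization on Dendrites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the emergence of local and global synaptic organization on
    dendrites from activity-dependent plasticity. Implements a neurotrophin
    (proBDNF/BDNF/MMP9/calcium) plasticity model and its generalized Hebbian
    reduction with distance-dependent heterosynaptic competition, a
    linear-nonlinear-Poisson encoding of spontaneous retinal-wave-like stimuli
    through species-specific Gabor receptive fields, structural plasticity with
    synapse turnover, dendritic morphologies (linear branches and SWC trees) and
    backpropagating action potentials, together with steady-state analytics
    (critical input correlation), organization metrics (orientation clustering,
    receptive-field overlap, circular dispersion, retinotopic offset) and
    protocol runners for burst-timing-dependent plasticity, phase diagrams and
    multi-day developmental simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
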