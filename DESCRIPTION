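Package: rivalnet
Title: Spiking Network Simulation and Analysis of Perceptual Rivalry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deterministic simulation of perceptual rivalry in networks of
    leaky integrate-and-fire neurons with spike-frequency adaptation.
    Provides three connectivity architectures (unstructured, discrete
    mutual inhibition, ring continuum with von Mises coupling), constant
    and Ornstein-Uhlenbeck feedforward drive protocols, a battery of
    perceptual and spiking variability measures (dominance durations,
    gamma fits, CV, skewness, Fano factors, spike-count correlations),
    balanced-state mean-field theory for one- and two-pool systems, and
    config-driven experiment runners with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    MASS,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
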