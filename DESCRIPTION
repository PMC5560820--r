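Package: ictonet
Title: Brain Network Ictogenicity and Virtual Resection on Networks of
    Neural Masses and Theta Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates noise-driven networks of nodes operating close to a
    saddle-node-on-invariant-circle (SNIC) bifurcation, using either the full
    Wendling neural mass model or its canonical (theta neuron) normal form, and
    quantifies the propensity of a network to generate epileptiform spiking via
    Brain Network Ictogenicity (BNI) and Node Ictogenicity (NI).  Includes
    generators for random, scale-free, small-world and rich-club graphs with a
    battery of node-importance measures, weighted Kendall rank comparisons of
    NI orderings, node-removal (virtual resection) strategies, inference of
    surrogate-corrected zero-lag correlation functional networks from
    multichannel recordings (IAAFT surrogates, Mann-Whitney U tests with
    Bonferroni-Holm correction), and weighted rich-club statistics with
    degree- and weight-preserving null ensembles.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    signal,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
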