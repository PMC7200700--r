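Package: ca1theta
Title: Biophysical Modelling and Circular Analysis of CA1 Theta Phase-Locking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to study how deep and superficial CA1 pyramidal cells lock
    to hippocampal theta oscillations. Provides a multicompartment
    Hodgkin-Huxley cell simulator with theta-modulated pathway inputs and
    genetic-algorithm conductance fitting; in-silico sublayer and interneuron
    manipulation experiments; circular phase statistics (Rayleigh,
    Watson-Williams and Harrison-Kanji tests, trough-peak index, surrogate
    modulation test); self-organizing-map classification of theta cycles into
    nested spectral components; a rank-order spike-sequence test; and a
    multinomial logistic-regression analysis of the determinants of phase
    preference. Synthetic-data generators for morphologies, LFP and spike
    trains make every stage testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    nnet,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
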