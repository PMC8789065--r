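Package: pottsim
Title: Codon-Level Evolutionary Simulation and Contact Prediction in
    Potts Sequence Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates experimental protein evolution as a mutation-selection
    Markov chain at the nucleotide level, with selection acting on aligned
    amino acid sequences through a Potts (direct coupling analysis) sequence
    landscape. Mutations are single-nucleotide changes, so the amino acids
    reachable at each site are constrained by the genetic code through the
    current codon. Provides calibration of the selection temperature and chain
    length against reference libraries, library-level statistics (site
    frequency spectra, energy-versus-distance profiles), Gaussian-DCA contact
    scoring with average-product correction and positive-predictive-value
    evaluation, parameter scans over selection strength, divergence and
    library depth, and a synthetic-landscape generator with a toy
    Boltzmann-machine learner so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
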