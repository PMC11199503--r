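Package: nfdsim
Title: Branching-Process Simulation of Neoantigen Evolution under
    Frequency-Dependent Immune Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic clone-indexed branching-process simulator of tumor
    growth under negative selection (NS) and negative frequency-dependent
    selection (NFDS) against neoantigens, with heritable subclonal immune
    escape, driver events, and immune-checkpoint-blockade intervention.
    Includes a virtual-sequencing noise model (binomial read sampling under
    configurable depth and purity), neoantigen clonality statistics
    (average cancer-cell fraction, antigenic load, Shannon diversity, the
    1/f power-law neutrality fit), survival analysis of virtual patients,
    and a patient-side cancer-cell-fraction estimator with confidence-
    interval-based clonal/subclonal classification for MAF-like mutation
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
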