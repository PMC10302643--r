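Package: TreeMPNN
Title: Tree-Structured Message-Passing Networks for Phosphine Ligand
    Rate-Constant Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts rate constants of Pd-catalyzed Sonogashira couplings of
    aryl bromides from topology-only descriptors. Phosphine ligands are encoded
    as phosphorus-rooted, CIP-prioritized layered trees aligned onto a fixed
    slot template, passed through a weight-tied, bias-free message-passing
    neural network; aryl bromide substrates are encoded as two-element Hammett
    sigma vectors. A constrained two-head readout decomposes the activation
    free energy into a ligand-only term and a ligand-substrate cooperative
    term, converted to and from rate constants with the Eyring equation.
    Includes a two-stage training protocol with fluctuation-based early
    termination, threshold-gated top-10 ensembling, fixed-test-set
    cross-validation, descriptor-swap baselines with non-negative linear
    regression, and a synthetic data generator with known additive
    free-energy ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'mpnn.R'
    'energy.R'
    'train.R'
    'baselines.R'
    'hammett.R'
    'io.R'
    'ligandTree.R'
    'serialize.R'
    'synthetic.R'
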