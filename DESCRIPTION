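Package: rbmsa
Title: Restricted Boltzmann Machines for Protein Sequence Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modeling of protein multiple sequence alignments with
    Restricted Boltzmann Machines (RBM) carrying Potts-like visible units and
    Gaussian, double-rectified-linear (dReLU) or Bernoulli hidden units. Provides
    alignment preprocessing and phylogenetic reweighting, training by persistent
    contrastive divergence, alternating Gibbs sampling including conditional
    (clamped hidden unit) and probability-boosted (duplicated model) sampling,
    annealed importance sampling estimates of the partition function, epistasis
    based residue-residue contact prediction with average product correction, and
    an exactly solvable cubic-lattice protein benchmark used as the package's
    synthetic data generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
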