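Package: rsapred
Title: Sequence-Based Prediction of Protein Relative Solvent Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts real-valued relative solvent accessibility (RSA) of
    protein residues from sequence-derived information alone. Five feature
    encodings (logistic-normalized PSSM profiles with terminal flags,
    local and global 3-state secondary-structure features, native-disorder
    probabilities, chain-length and residue-position descriptors, and six
    physicochemical propensity scales) are assembled over a sliding window
    whose positions are weighted by least-squares-fitted neighbor
    influence. Prediction uses epsilon-support-vector regression with a
    Gaussian kernel, with hyperparameters tuned by particle swarm
    optimization against chain-level cross-validated error; a grid-search
    baseline is included. Evaluation covers mean absolute error, Pearson
    correlation, two-state (buried/exposed) accuracy across thresholds,
    and per-residue-type error summaries. A synthetic-data module emulates
    every upstream file format (FASTA, PSI-BLAST ASCII PSSM, PSIPRED
    '.ss2', DISOPRED tables, RSA tracks) with known statistical structure
    so the whole pipeline is testable without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    optparse,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
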