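Package: mirstart
Title: Mature miRNA 5' Start-Site Prediction from Pre-miRNA Hairpins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates the 5' mature miRNA start position within a pre-miRNA
    hairpin. Candidate start sites are enumerated by a 1-nt sliding window,
    each candidate is encoded as a 110-dimensional vector of sequence and
    secondary-structure features built around the miRNA:miRNA* duplex
    alignment, and candidates are ranked by an AdaBoost-weighted ensemble of
    probability-calibrated radial-basis-function support vector machines.
    Class imbalance between the one true start and the many decoy windows is
    handled by k-means undersampling of negatives (centroid-nearest
    representatives) and iterative augmentation of the training subset with
    previously misclassified examples. Includes readers for FASTA, Vienna
    dot-bracket and tabular annotations, a synthetic stem-loop generator with
    a planted, learnable start signature, position-deviation evaluation
    metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
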