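Package: esiden
Title: Protein Backbone Torsion-Angle Prediction from Evolutionary Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein backbone torsion angles (phi, psi) from sequence
    profiles using four evolutionary-signature features (per-column relative
    entropy, degree of conservation, position-specific substitution
    probabilities from independent-site Potts fields, and a triplet-conditioned
    Ramachandran basin potential reduced to a compact embedding) together with
    classic features (amino-acid one-hot, seven physicochemical properties,
    PSI-BLAST PSSM). A parallel LSTM/BiLSTM recurrent network, implemented
    natively with full backpropagation-through-time and Adam optimization,
    regresses the sine and cosine of each angle; predictions are decoded with
    the quadrant-aware arctangent and scored with the wrap-aware mean absolute
    angular error, pooled and per secondary-structure class. Includes readers
    for FASTA, aligned FASTA/A3M, PDB backbones and PSI-BLAST ASCII PSSM files,
    a synthetic-data generator (conservation-controlled alignments and ideal-
    geometry backbones built from prescribed torsions), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
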