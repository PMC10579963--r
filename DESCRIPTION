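Package: pepgen
Title: Generative Design and Screening of NLRP3-Inhibitory Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A toolkit for de novo design of short NLRP3 inflammasome
    inhibitory peptides. Implements corpus preparation (length filtering,
    greedy identity-based redundancy reduction, padding and encoding), a
    character-level LSTM peptide language model trained with categorical
    cross-entropy and the Adam optimizer (with k-fold cross-validation over
    an architecture grid and temperature-controlled sampling), global
    physicochemical descriptors (charge, Eisenberg hydrophobicity and
    hydrophobic moment, isoelectric point, aromaticity, aliphatic and
    instability indices) with min-max scaling, centroid distances and
    Welch's t-tests, basis-set circular-dichroism spectrum calculation with
    an ellipticity filter, and contact-variance screening of
    molecular-dynamics-derived peptide-receptor contacts with
    binding-energy thresholds, ranking, and cell-penetrating-peptide
    fusion. Synthetic data generators make every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    withr
Config/testthat/edition: 3
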