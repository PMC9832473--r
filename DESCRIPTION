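Package: pepiso
Title: Structure-Based Isoelectric Point Calculation for Natural and Modified Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculates isoelectric points (pI), charge versus pH curves, net
    charge at physiological pH and isoelectric intervals for peptides from
    their chemical structure or their one-letter sequence. Chemical structures
    are fragmented at backbone amide bonds, the capped fragments are matched
    against substructure templates of the canonical amino acids, and ionizable
    groups of noncanonical fragments are assigned pKa values with an ordered
    table of substructure rules. Net charge follows the independent-site
    Henderson-Hasselbalch model and pI is located by bisection; results are
    reported as a consensus (mean and standard deviation) over eight published
    pKa sets for the canonical residues.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    ChemmineOB,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
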