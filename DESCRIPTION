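Package: pipodesign
Title: Design of Pop-In/Pop-Out Genome-Editing Plasmids for Budding Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated design of marker-free pop-in/pop-out (PIPO)
    genome-editing plasmids for Saccharomyces cerevisiae. Given a gene locus
    (1,000 bp upstream flank, ORF, 1,000 bp downstream flank), a vector
    backbone with a multiple cloning site, and a preference-ordered
    restriction-enzyme list, the package enumerates candidate linearization
    cut sites, sizes pop-in and pop-out homology arms under a user-set
    pop-out/pop-in ratio, assembles the minimal synthesizable insert for ORF
    deletion or N-/C-terminal tagging with all restriction-site constraints
    satisfied, and verifies each design by simulating the pop-in integration
    and pop-out excision recombination events. Includes a deterministic
    synthetic-fixture generator with planted restriction-site geometry, a
    genome-wide batch driver, TSV/JSON/FASTA/GenBank reporting, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
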