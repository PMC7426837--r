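Package: digenomeR
Title: Strand-Aware Digenome-Seq Analysis for Cas12a Cytidine Base Editors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects genome-wide single-strand-break (SSB) sites from
    whole-genome sequencing of DNA treated in vitro with a catalytically
    dead Cas12a (Cpf1) cytidine base editor and USER enzyme. Builds
    strand-separated 5'-end pileups from aligned reads, calls positions
    with straight-alignment evidence of a nick, filters candidates by
    PAM- and bulge-aware homology to the crRNA protospacer, quantifies
    amplicon editing frequencies and derived specificity metrics
    (relative activity, OTI index, specificity ratio), builds sequence
    logos from captured sites, and ships a read-digestion simulator so
    the whole pipeline is testable on synthetic genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
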