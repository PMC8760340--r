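Package: cdmine
Title: Mining and Classification of Cyclodextrin Glucanotransferases and
    CM-CD Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence-based discovery and classification of cyclomaltodextrin
    glucanotransferases (CGTases, EC 2.4.1.19) and of the carbohydrate
    metabolism via cyclodextrins (CM-CD) gene clusters that encode them.
    Provides a rule-based lipoprotein (signal peptidase II) signal-peptide
    detector, conserved-sequence-region (CSR I-VII) motif transfer and
    diagnostic-residue classification for glycoside hydrolase family 13,
    domain-architecture calling (ABC, ABCE-CBM20, ABCDE-CBM20, ABCDE-arch),
    global-alignment percent identity with a novelty filter, neighbor-joining
    phylogenetics with bootstrap support and monophyly tests, detection of
    CM-CD gene clusters and sigma-promoter boxes in annotated genomes, and a
    deterministic synthetic-genome generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
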