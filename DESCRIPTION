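Package: paleodup
Title: Subgenome Synteny, Duplicate Gene Divergence and Ks Dating After
    Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Paleodup", "Maintainers", email = "maintainers@paleodup.org",
           role = c("aut", "cre"))
Description: Dissects the evolutionary history of a descendant genome against
    a paleodiploid reference: collinear (synteny) block detection by anchor
    chaining, partition of blocks into two non-overlapping subgenomes,
    derivation of syntenic ortholog, whole-genome-duplication (WGD) duplicate
    and tandem paralog gene pairs, fractionation accounting, functional
    divergence classification from annotation-term sets
    (conserved / sub-functionalized / neo-functionalized), Ka/Ks selection
    analysis with a Nei-Gojobori (NG86) estimator, and Ks-distribution peak
    dating of duplication events.  Ships a genome-evolution simulator with
    ground-truth labels so the whole pipeline is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
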