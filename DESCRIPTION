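Package: pseudochron
Title: Detection and Dating of Gene Inactivation from Codon Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gene loss in protein-coding genes across a
    phylogeny. Detects and classifies open-reading-frame-disrupting mutations
    (initiation-codon loss, frameshift indels, premature stop codons, splice-site
    GT/AG mutations, exon deletions) in codon-aware alignments against an intact
    reference; places shared lesions on a species tree under Dollo parsimony;
    fits Goldman-Yang codon substitution models with branch-specific dN/dS by
    maximum likelihood, including a four-model ladder with likelihood-ratio
    tests for relaxed selection; and converts branch dN/dS estimates plus
    divergence-time bounds into gene-inactivation time intervals via the
    mixed-branch neutral-time equations. A codon-alignment simulator with known
    omega histories and planted lesions supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    seqinr,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
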