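Package: posiselect
Title: Genome-Wide Detection of Positively Selected Genes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for genome-wide scans of protein-coding
    genes for positive selection on a chosen phylogenetic branch. Builds
    ortholog catalogs by group-to-group best-bidirectional-hit assignment,
    selects one transcript isoform per species relative to an anchor species,
    aligns coding sequences on codon level, removes unreliable alignment
    columns, infers a species tree by chunked parsimony with majority-rule
    consensus, runs the branch-site likelihood-ratio test of positive
    selection under a codon substitution model, applies plausibility filters
    and multiple-testing correction, and ranks candidate genes. A built-in
    codon-evolution simulator with indels generates gene families under
    configurable site-wise selection schemes for validation of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
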