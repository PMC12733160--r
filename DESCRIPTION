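Package: plastevo
Title: Comparative Plastome Structure, Codon Usage Bias and Selection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of plant chloroplast genomes
    (plastomes): detection of the quadripartite LSC/IRb/SSC/IRa architecture
    from exact inverted repeats, extraction and curation of protein-coding
    sequences under the plastid genetic code, a codon-usage-bias battery
    (relative synonymous codon usage, Wright's effective number of codons with
    the expected GC3s curve, positional GC content, parity-rule-2 indices,
    neutrality regression), correspondence analysis of RSCU profiles,
    MISA-style perfect microsatellite mining with genomic-context
    classification and presence/absence clustering, Nei-Gojobori (NG86) Ka/Ks
    estimation with selection-category statistics, gene-order synteny,
    neighbor-joining phylogenies with branch-rate summaries, and a synthetic
    plastome generator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
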