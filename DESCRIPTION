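Package: plastomics
Title: Comparative Chloroplast Genome Structure, Repeat and Marker Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of angiosperm chloroplast
    (plastid) genomes and for the evaluation of chloroplast molecular
    markers. Detects the quadripartite LSC/IRb/SSC/IRa architecture and
    reports junction gene distances and boundary pseudogenes; mines
    perfect microsatellites (MISA-style thresholds), dispersed repeats
    (forward, reverse, complement and palindromic classes) and tandem
    repeats under alignment-score filtering; computes per-region
    nucleotide diversity (pi) and the total number of mutations (eta)
    from multiple alignments; and computes the per-locus discriminating
    power D_j used to compare cpSSR fragment-size markers against SNV
    haplotype markers for variety profiling. A synthetic plastome
    generator with full ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
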