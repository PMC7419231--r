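Package: dcjmedian
Title: Genome Rearrangement Distances, Ancestral Medians and Synteny-Based
    Divergence Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative genomics on signed synteny-block orders. Encodes
    genomes as signed block orders (GRIMM-like text or TSV), computes pairwise
    double-cut-and-join (DCJ) genomic distances via the adjacency
    ("breakpoint") graph, reconstructs ancestral genomes as DCJ medians with
    lower/upper bound formulas and an exact branch-and-bound or heuristic
    search, chains three-genome orthologue tables into synteny blocks, paints
    extant chromosomes by ancestral chromosome, places an ultrametric ancestor
    on the median-to-outgroup path, and dates divergences by Gaussian-mixture
    fitting of ln(Ks) with BIC model choice. Includes a seeded simulator of
    rearrangement histories (reversal, translocation, fusion, fission,
    transposition) with subgenome-style fractionation so every stage is
    verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
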