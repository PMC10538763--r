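Package: xrecomb
Title: Pedigree-Based Estimation of X-Chromosome Recombination and
    Mutation Rates
Version: 1.0.0
Authors@R:
    person("xrecomb", "developers", email = "xrecomb@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of recombination rates between
    adjacent X-chromosomal markers (and per-marker mutation rates) from
    pedigree genotype data in PLINK PED format. Informative three-generation
    (type I) and two-generation (type II) families are extracted from
    arbitrary pedigrees, females are phased by subtraction of the paternal
    haplotype, and the exact inheritance-vector likelihood is computed either
    by direct enumeration or by a linear-time forward (dynamic-programming)
    recursion, with branch-and-prune summation over maternal phasings for
    type II families. Supports mixed panels of STR and non-STR (e.g. SNP,
    indel) markers via a stepwise and a transition/transversion mutation
    kernel, and includes a pedigree simulator with known ground truth plus a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
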