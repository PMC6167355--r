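Package: xstrpop
Title: Forensic and Population Genetics of X-Chromosomal STR Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sex-aware analysis of X-chromosomal short tandem repeat (X-STR)
    genotype data. Estimates allele frequencies by stratum (females, males,
    pooled X chromosomes) and male linkage-group haplotype frequencies by
    direct counting; computes the full forensic parameter suite (gene and
    haplotype diversity, match probability, polymorphism information content,
    powers of discrimination in males and females, and the Krueger, Kishida,
    Desmarais and Desmarais-duo mean exclusion chances) with combined powers
    reported at full precision; runs exact tests for Hardy-Weinberg
    equilibrium in females (Markov-chain exact test), pairwise linkage
    disequilibrium in females (EM-based permutation test) and males (haploid
    Markov-chain exact test), and male/female differentiation (Fst with
    permutation p-values); and compares populations through Nei's standard
    genetic distance, principal component analysis, classical
    multidimensional scaling and Neighbor-Joining trees. A synthetic-data
    generator reproduces the statistical structure of an X-STR study cohort
    (hemizygous males, diploid females, microvariant allele labels,
    within-group haplotype association, Balding-Nichols population
    divergence) so every stage is testable without casework data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
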