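Package: postglacial
Title: Coalescent Reconstruction of Postglacial Colonization from ddRAD SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct the colonization history of postglacial
    fish populations from reduced-representation (ddRAD) SNP data: a site
    filter cascade (presence, per-population completeness, observed
    heterozygosity, depth, missingness, minor allele frequency, exact
    Hardy-Weinberg tests, one SNP per locus), diversity and differentiation
    statistics (expected/observed heterozygosity, nucleotide diversity,
    rarefied allelic richness, Weir & Cockerham F_ST with permutation tests,
    Dxy, windowed F_ST outlier scans, PCA with per-SNP eigenvector
    correlations), a backward-time coalescent simulator for multi-deme
    demographies with population splits and pulse admixture, demographic
    inference by composite likelihood on the multidimensional minor-allele
    site frequency spectrum with hierarchical model building and parametric
    bootstrap confidence intervals, and median-joining haplotype networks for
    mitochondrial alignments. Includes a synthetic-data generator emulating a
    multi-lake European whitefish study design so the full pipeline runs
    without raw sequence archives.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
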