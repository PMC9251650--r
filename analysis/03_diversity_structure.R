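#!/usr/bin/env Rscript
# Step 3: diversity and population structure.
#
# Per-population diversity (rarefied allelic richness at 3 diploids --
# the smallest sample -- expected/observed heterozygosity, nucleotide
# diversity over variant + invariant sites), pairwise Weir & Cockerham
# F_ST with permutation tests, Dxy, and a PCA with per-SNP eigenvector
# correlations.

suppressMessages(library(postglacial))
dir.create("results", showWarnings = FALSE)

g <- read_vcf("results/filtered.vcf", "results/popmap.txt")

div <- diversity_stats(g, invariant_sites_per_locus = 142, min_diploids = 3)
cat("Diversity table:\n")
print(div, digits = 3)
write.table(div, "results/diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nPairwise F_ST / Dxy (200 permutations per pair) ...\n")
ps <- pairwise_stats(g, n_perm = 200, seed = 1)
print(round(ps$fst, 3))
write.table(round(ps$fst, 4), "results/fst_matrix.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
write.table(signif(ps$dxy, 4), "results/dxy_matrix.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
write.table(ps$p_value, "results/fst_pvalues.tsv", sep = "\t",
            quote = FALSE, col.names = NA)

pca <- pca_with_snp_correlation(g, n_components = 3)
cat("\nPCA explained variance (first 3):",
    paste0(round(100 * pca$explained[1:3], 1), "%", collapse = ", "), "\n")
scores <- data.frame(sample = rownames(pca$scores), pop = g$pops,
                     pca$scores)
write.table(scores, "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
corr <- data.frame(g$sites[, c("chrom", "pos")], pca$snp_correlation)
write.table(corr, "results/pca_snp_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote diversity.tsv, fst_matrix.tsv, dxy_matrix.tsv, pca_*.tsv\n")
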