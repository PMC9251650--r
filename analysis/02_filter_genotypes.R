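#!/usr/bin/env Rscript
# Step 2: apply the ddRAD site-filter cascade.
#
# Rules (in order): locus presence across populations, per-population
# completeness, maximum observed heterozygosity 0.6, per-genotype depth in
# [5, 30] and site mean depth in [10, 30], <= 15% missing calls, minor
# allele frequency >= 0.05, exact Hardy-Weinberg tests within populations,
# and one SNP per locus.  Outputs: filtered VCF and a per-rule removal
# report.

suppressMessages(library(postglacial))
dir.create("results", showWarnings = FALSE)

g <- read_vcf("results/study/data.vcf", "results/study/popmap.txt")
print(g)

cfg <- filter_config(min_pops = 9, min_prop_per_pop = 0.8,
                     max_obs_het = 0.6, min_maf = 0.05,
                     min_gt_depth = 5, min_mean_depth = 10,
                     max_gt_depth = 30, max_mean_depth = 30,
                     max_missing_frac = 0.15,
                     hwe_alpha = 0.001, hwe_pop_frac = 0.5)
res <- apply_filters(g, cfg)
cat("\nRemoval report (", attr(res$report, "masked_genotypes"),
    "depth-masked genotype calls ):\n")
print(res$report)
cat("Sites:", attr(res$report, "input_sites"), "->",
    attr(res$report, "output_sites"), "\n")

write.table(res$report, "results/filter_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_vcf(res$genotypes, "results/filtered.vcf",
          popmap_path = "results/popmap.txt")
cat("Wrote results/filtered.vcf and results/filter_report.tsv\n")
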