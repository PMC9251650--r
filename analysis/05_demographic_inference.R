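#!/usr/bin/env Rscript
# Step 5: coalescent demographic inference from the MSFS.
#
# The six backbone populations are down-sampled to seven fully genotyped
# diploids each (no missing data allowed in a spectrum), the folded
# multidimensional SFS is built with its monomorphic entry corrected to
# the surveyed sequence length, and the key parameters of the six-deme
# history are re-estimated by profiling the composite likelihood on
# informative two-deme marginal spectra.  Ages assume 3.5 years per
# generation.

suppressMessages(library(postglacial))
dir.create("results", showWarnings = FALSE)

# the inference dataset keeps low-frequency sites: same cascade as the
# pop-gen dataset but with the MAF filter disabled; thinning to one SNP
# per locus is done afterwards so the surveyed length can be kept
# consistent with it
g <- read_vcf("results/study/data.vcf", "results/study/popmap.txt")
inf <- apply_filters(g, filter_config(min_pops = 9, min_prop_per_pop = 0.8,
                                      max_obs_het = 0.6, min_maf = 0,
                                      min_gt_depth = 5, min_mean_depth = 10,
                                      max_gt_depth = 30, max_mean_depth = 30,
                                      max_missing_frac = 0.15,
                                      hwe_alpha = 0.001,
                                      one_snp_per_locus = FALSE))$genotypes
demes <- c("NOR", "BAL", "ALP", "LOM", "LTE", "RTA")
g6 <- subset_genotypes(inf, samples = which(inf$pops %in% demes))
n_sites_before <- ncol(g6$geno)
g6 <- downsample_genotypes(g6, 7, seed = 1)
p_complete <- ncol(g6$geno) / n_sites_before
s_all <- ncol(g6$geno)
g6 <- subset_genotypes(g6, sites = !duplicated(g6$sites$locus))
cat("Down-sampled to", nrow(g6$geno), "diploids;", s_all,
    "fully genotyped SNPs,", ncol(g6$geno), "after one-per-locus thinning\n")

truth <- jsonlite::fromJSON("results/study/truth.json",
                            simplifyDataFrame = FALSE)
# surveyed length for the monomorphic correction: the generating sequence
# length scaled by (i) the complete-case fraction -- invariant sites drop
# out of complete-case data at the same per-site rate as SNPs -- and (ii)
# the one-SNP-per-locus thinning fraction, so the per-site SNP density of
# the spectrum stays that of the data
total_sites <- round(truth$n_loci * truth$locus_length * p_complete *
                       ncol(g6$geno) / s_all)
obs <- correct_monomorphic(msfs_from_genotypes(g6, demes), total_sites)
print(obs)
write_msfs(obs, "results/observed.msfs")
obs6 <- project_msfs(obs, 6)          # six chromosomes per deme

mod <- six_pop_model()
est <- list()
prof <- function(spec, grid, demes_pair) {
  m <- msfs_from_genotypes(g6, demes_pair)
  m <- correct_monomorphic(m, total_sites)
  pr <- profile_composite_likelihood(m, mod, spec, grid = grid,
                                     n_sims = 10000, seeds = 1:2)
  attr(pr, "estimate")
}
cat("\nProfiling key parameters (this takes a few minutes) ...\n")
est$T_NOR <- prof(free_param("T", "split_time", "NOR", 15000, 35000),
                  seq(15000, 35000, by = 1000), c("NOR", "ALP"))
est$T_LOM <- prof(free_param("T", "split_time", "LOM", 12000, 25000),
                  seq(12000, 25000, by = 650), c("LOM", "ALP"))
est$T_RTA <- prof(free_param("T", "split_time", "RTA", 2000, 8000),
                  seq(2000, 8000, by = 300), c("LTE", "RTA"))
est$alpha_NOR_BAL <- prof(free_param("a", "pulse_alpha", "NOR:BAL", 0, 1),
                          seq(0, 1, by = 0.05), c("NOR", "BAL"))

tab <- data.frame(
  parameter = names(est),
  estimate = round(unlist(est), 3),
  generating = c(26247, 18674, 3887, 0.46))
tab$age_ky <- ifelse(tab$parameter == "alpha_NOR_BAL", NA,
                     generations_to_ky(tab$estimate))
print(tab, row.names = FALSE)
write.table(tab, "results/demographic_estimates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/observed.msfs and results/demographic_estimates.tsv\n")
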