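#' Per-population diversity statistics
#'
#' Observed heterozygosity is the mean fraction of heterozygous calls among
#' genotyped samples; expected heterozygosity uses the small-sample unbiased
#' gene diversity `(2n/(2n-1)) * (1 - sum p^2)` averaged over variant
#' sites; nucleotide diversity is the average pairwise difference per site,
#' with the denominator including invariant sequence (`n_loci *
#' invariant_sites_per_locus + n_variant_sites`), as ddRAD loci carry mostly
#' invariant bases.
#'
#' @param g a [genotype_matrix].
#' @param invariant_sites_per_locus invariant bases carried per locus.
#' @param min_diploids rarefaction depth for allelic richness, in diploids.
#' @return data.frame with one row per population: `n` (diploids), `A_R`,
#'   `H_E`, `H_O`, `pi`.
#' @export
diversity_stats <- function(g, invariant_sites_per_locus = 142,
                            min_diploids = 3) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- unique(g$pops)
  n_loci <- length(unique(g$sites$locus))
  total_len <- n_loci * invariant_sites_per_locus + ncol(g$geno)
  ar <- rarefied_allelic_richness(g, min_diploids = min_diploids)
  out <- lapply(pops, function(p) {
    sub <- g$geno[g$pops == p, , drop = FALSE]
    n_gt <- colSums(!is.na(sub))
    use <- n_gt >= 1
    if (!any(use))
      return(data.frame(pop = p, n = nrow(sub), A_R = NA_real_,
                        H_E = NA_real_, H_O = NA_real_, pi = NA_real_))
    het <- colSums(sub == 1L, na.rm = TRUE)[use] / n_gt[use]
    alt <- colSums(sub, na.rm = TRUE)[use]
    genes <- 2 * n_gt[use]
    pfreq <- alt / genes
    gene_div <- ifelse(genes > 1,
                       genes / (genes - 1) * 2 * pfreq * (1 - pfreq), 0)
    # average pairwise difference at a site equals the unbiased gene
    # diversity; invariant sites contribute zero to the numerator
    data.frame(pop = p, n = nrow(sub),
               A_R = ar[p],
               H_E = mean(gene_div),
               H_O = mean(het),
               pi = sum(gene_div) / total_len)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a subsample of `2 * min_diploids`
#' genes, computed per site from the exact subsampling expectation
#' `sum_a [1 - C(N - N_a, k) / C(N, k)]` and averaged over the sites where
#' the population has at least `min_diploids` genotyped diploids (others
#' are skipped for that population).
#'
#' @param g a [genotype_matrix].
#' @param min_diploids rarefaction depth in diploid individuals.
#' @return named numeric vector of per-population A_R (in `[1, 2]` for
#'   biallelic data).
#' @export
rarefied_allelic_richness <- function(g, min_diploids = 3) {
  stopifnot(inherits(g, "genotype_matrix"))
  k <- 2 * min_diploids
  pops <- unique(g$pops)
  out <- vapply(pops, function(p) {
    sub <- g$geno[g$pops == p, , drop = FALSE]
    n_gt <- colSums(!is.na(sub))
    use <- 2 * n_gt >= k & n_gt > 0
    if (!any(use)) return(NA_real_)
    alt <- colSums(sub, na.rm = TRUE)[use]
    N <- 2 * n_gt[use]
    p_alt_absent <- exp(lchoose(N - alt, k) - lchoose(N, k))
    p_ref_absent <- exp(lchoose(alt, k) - lchoose(N, k))
    mean((1 - p_alt_absent) + (1 - p_ref_absent))
  }, numeric(1))
  names(out) <- pops
  out
}
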