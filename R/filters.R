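#' SNP filter cascade configuration
#'
#' Defaults mirror a standard ddRAD pipeline: a locus must be present in at
#' least `min_pops` populations, with at least `min_prop_per_pop` of the
#' samples genotyped in each counted population; sites with observed
#' heterozygosity above `max_obs_het` (paralog signal), minor allele
#' frequency below `min_maf`, per-site missingness above
#' `max_missing_frac`, genotype depths outside `[min_gt_depth,
#' max_gt_depth]` or site mean depths outside `[min_mean_depth,
#' max_mean_depth]` are removed; sites out of exact Hardy-Weinberg
#' equilibrium (p < `hwe_alpha`) in more than `hwe_pop_frac` of the
#' populations with data are removed; finally one SNP per locus is kept.
#'
#' @param min_pops minimum number of populations a locus must be present in.
#' @param min_prop_per_pop minimum proportion of genotyped samples within a
#'   population for the locus to count as present there.
#' @param max_obs_het maximum observed heterozygosity at a site.
#' @param min_maf minimum global minor allele frequency.
#' @param min_gt_depth,max_gt_depth per-genotype depth bounds; calls outside
#'   are set to missing.
#' @param min_mean_depth,max_mean_depth per-site mean depth bounds.
#' @param max_missing_frac maximum fraction of missing genotypes per site.
#' @param hwe_alpha,hwe_pop_frac exact-test threshold and the fraction of
#'   populations that must fail it for a site to be dropped.
#' @param one_snp_per_locus keep only the first SNP (by position) per locus.
#' @return a `filter_config` object.
#' @export
filter_config <- function(min_pops = 9, min_prop_per_pop = 0.8,
                          max_obs_het = 0.6, min_maf = 0.05,
                          min_gt_depth = 5, min_mean_depth = 10,
                          max_gt_depth = 30, max_mean_depth = 30,
                          max_missing_frac = 0.15,
                          hwe_alpha = 0.001, hwe_pop_frac = 0.5,
                          one_snp_per_locus = TRUE) {
  cfg <- list(min_pops = min_pops, min_prop_per_pop = min_prop_per_pop,
              max_obs_het = max_obs_het, min_maf = min_maf,
              min_gt_depth = min_gt_depth, min_mean_depth = min_mean_depth,
              max_gt_depth = max_gt_depth, max_mean_depth = max_mean_depth,
              max_missing_frac = max_missing_frac,
              hwe_alpha = hwe_alpha, hwe_pop_frac = hwe_pop_frac,
              one_snp_per_locus = one_snp_per_locus)
  fracs <- c(cfg$min_prop_per_pop, cfg$max_obs_het, cfg$min_maf,
             cfg$max_missing_frac, cfg$hwe_pop_frac)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (any(c(cfg$min_gt_depth, cfg$min_mean_depth) < 0))
    stop("depth bounds must be non-negative")
  if (cfg$min_gt_depth > cfg$max_gt_depth ||
      cfg$min_mean_depth > cfg$max_mean_depth)
    stop("min depth exceeds max depth")
  structure(cfg, class = "filter_config")
}

#' Apply the site filter cascade
#'
#' Rules run in a fixed order -- presence, per-population completeness,
#' observed heterozygosity, depth, missingness, minor allele frequency,
#' Hardy-Weinberg, one SNP per locus -- and each site is charged to the
#' first rule that removes it.  The depth step first masks individual
#' genotypes outside the per-genotype bounds (so later rules see them as
#' missing), then removes sites whose mean depth is out of bounds.  Depth
#' rules are skipped with a warning when the matrix has no depth layer.
#'
#' @param g a [genotype_matrix].
#' @param cfg a [filter_config()].
#' @return list with `genotypes` (the filtered [genotype_matrix]) and
#'   `report`, a data.frame of sites removed per rule (plus the count of
#'   depth-masked genotype calls as an attribute `masked_genotypes`).
#' @export
apply_filters <- function(g, cfg = filter_config()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "filter_config"))
  pops <- unique(g$pops)
  n_in <- ncol(g$geno)
  removed <- c(presence = 0, pop_completeness = 0, obs_het = 0, depth = 0,
               missingness = 0, maf = 0, hwe = 0, one_snp_per_locus = 0)
  masked <- 0L

  per_pop <- function(gm, f) {
    out <- vapply(pops, function(p)
      f(gm$geno[gm$pops == p, , drop = FALSE]), numeric(ncol(gm$geno)))
    matrix(out, nrow = ncol(gm$geno))      # sites x populations
  }

  # presence: locus genotyped in >= min_pops populations
  pres <- per_pop(g, function(x) colSums(!is.na(x)) > 0)
  keep <- rowSums(pres) >= min(cfg$min_pops, length(pops))
  removed["presence"] <- sum(!keep)
  g <- subset_genotypes(g, sites = keep)

  # per-population completeness: >= min_prop genotyped in >= min_pops pops
  prop <- per_pop(g, function(x) colMeans(!is.na(x)))
  keep <- rowSums(prop >= cfg$min_prop_per_pop) >= min(cfg$min_pops,
                                                       length(pops))
  removed["pop_completeness"] <- sum(!keep)
  g <- subset_genotypes(g, sites = keep)

  # observed heterozygosity
  het <- colMeans(g$geno == 1L, na.rm = TRUE)
  keep <- is.na(het) | het <= cfg$max_obs_het
  removed["obs_het"] <- sum(!keep)
  g <- subset_genotypes(g, sites = keep)

  # depth: mask bad genotype calls, then filter on site mean depth
  if (is.null(g$depth)) {
    if (any(is.finite(c(cfg$min_gt_depth, cfg$min_mean_depth))))
      warning("no depth information: depth rules skipped")
  } else {
    bad <- !is.na(g$depth) & !is.na(g$geno) &
      (g$depth < cfg$min_gt_depth | g$depth > cfg$max_gt_depth)
    masked <- sum(bad)
    g$geno[bad] <- NA_integer_
    dp <- g$depth
    dp[is.na(g$geno)] <- NA
    mean_dp <- colMeans(dp, na.rm = TRUE)
    keep <- !is.na(mean_dp) & mean_dp >= cfg$min_mean_depth &
      mean_dp <= cfg$max_mean_depth
    removed["depth"] <- sum(!keep)
    g <- subset_genotypes(g, sites = keep)
  }

  # missingness
  miss <- colMeans(is.na(g$geno))
  keep <- miss <= cfg$max_missing_frac
  removed["missingness"] <- sum(!keep)
  g <- subset_genotypes(g, sites = keep)

  # minor allele frequency (global, pairwise deletion)
  ac <- allele_counts(g, pops = pops)
  alt <- colSums(ac$alt); n <- colSums(ac$n)
  maf <- pmin(alt, n - alt) / pmax(n, 1)
  keep <- n > 0 & maf >= cfg$min_maf
  removed["maf"] <- sum(!keep)
  g <- subset_genotypes(g, sites = keep)

  # Hardy-Weinberg within populations
  if (!is.na(cfg$hwe_alpha) && ncol(g$geno)) {
    flag <- hwe_filter(g, alpha = cfg$hwe_alpha, pop_frac = cfg$hwe_pop_frac)
    removed["hwe"] <- sum(flag)
    g <- subset_genotypes(g, sites = !flag)
  }

  # one SNP per locus: first by position
  if (cfg$one_snp_per_locus && ncol(g$geno)) {
    keep <- !duplicated(g$sites$locus)
    removed["one_snp_per_locus"] <- sum(!keep)
    g <- subset_genotypes(g, sites = keep)
  }

  if (ncol(g$geno) == 0) warning("no sites survived the filter cascade")
  report <- data.frame(rule = names(removed), removed = as.integer(removed),
                       row.names = NULL)
  attr(report, "masked_genotypes") <- masked
  attr(report, "input_sites") <- n_in
  attr(report, "output_sites") <- ncol(g$geno)
  list(genotypes = g, report = report)
}

#' Exact Hardy-Weinberg test (Wigginton-Cutler-Abecasis)
#'
#' Two-sided exact test on diploid genotype counts: the p-value is the total
#' probability, under the conditional distribution of heterozygote counts
#' given allele counts, of outcomes no more probable than the observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom).
#' @return p-value in `(0, 1]`; monomorphic data give 1.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_b <- 2 * n_bb + n_ab             # minor allele copies
  if (n_b > n) { tmp <- n_aa; n_aa <- n_bb; n_bb <- tmp; n_b <- 2 * n - n_b }
  if (n == 0 || n_b == 0) return(1)
  hets <- seq(n_b %% 2, n_b, by = 2)
  # unnormalized conditional probabilities via log factorials
  lp <- lfactorial(n) - lfactorial((n_b - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (n_b + hets) / 2) + hets * log(2)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  sum(p[p <= obs + 1e-12])
}

#' Flag sites out of Hardy-Weinberg equilibrium within populations
#'
#' A site is flagged when the exact test rejects (p < `alpha`) in more than
#' `pop_frac` of the populations with at least two genotyped diploids at
#' the site.  Sites monomorphic within a population give p = 1 there.
#'
#' @param g a [genotype_matrix].
#' @param alpha per-population significance threshold.
#' @param pop_frac fraction of populations with data that must reject.
#' @return logical site mask (TRUE = flagged for removal).
#' @export
hwe_filter <- function(g, alpha = 0.001, pop_frac = 0.5) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- unique(g$pops)
  S <- ncol(g$geno)
  n_rej <- n_dat <- integer(S)
  for (p in pops) {
    sub <- g$geno[g$pops == p, , drop = FALSE]
    n0 <- colSums(sub == 0L, na.rm = TRUE)
    n1 <- colSums(sub == 1L, na.rm = TRUE)
    n2 <- colSums(sub == 2L, na.rm = TRUE)
    has <- (n0 + n1 + n2) >= 2
    pv <- rep(1, S)
    for (i in which(has)) pv[i] <- hwe_exact_test(n0[i], n1[i], n2[i])
    n_dat <- n_dat + has
    n_rej <- n_rej + (has & pv < alpha)
  }
  n_dat > 0 & n_rej > pop_frac * n_dat
}
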