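test_that("heterozygosity and pi match hand computations", {
  # one site, genotypes {0, 1} in 2 diploids: p = 0.75 / 0.25,
  # H_E = (4/3)(1 - 0.625) = 0.5, H_O = 0.5
  g <- toy_genotypes(matrix(c(0L, 1L), 2, 1), rep("A", 2))
  d <- diversity_stats(g, invariant_sites_per_locus = 0)
  expect_equal(d$H_E, 0.5)
  expect_equal(d$H_O, 0.5)
  expect_equal(d$pi, 0.5)            # one variant site, length 1
  # monomorphic population
  g0 <- toy_genotypes(matrix(0L, 3, 2), rep("A", 3))
  d0 <- diversity_stats(g0, invariant_sites_per_locus = 10)
  expect_equal(d0$H_E, 0); expect_equal(d0$H_O, 0); expect_equal(d0$pi, 0)
})

test_that("rarefied allelic richness matches exhaustive enumeration", {
  # fixed site
  g <- toy_genotypes(matrix(2L, 4, 1), rep("A", 4))
  expect_equal(unname(rarefied_allelic_richness(g, min_diploids = 3)), 1)
  # N = 8 genes, allele counts (6, 2), subsample 6 genes
  g2 <- toy_genotypes(matrix(c(2L, 2L, 1L, 1L), 4, 1), rep("A", 4))
  expect_equal(unname(rarefied_allelic_richness(g2, min_diploids = 3)),
               ar_enumeration_oracle(alt = 6, N = 8, k = 6),
               tolerance = 1e-12)
  # random instances
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    geno <- matrix(sample(0:2, n, replace = TRUE), n, 1)
    gi <- toy_genotypes(geno, rep("A", n))
    k <- sample(1:(n - 1), 1)
    expect_equal(unname(rarefied_allelic_richness(gi, min_diploids = k)),
                 ar_enumeration_oracle(sum(geno), 2 * n, 2 * k),
                 tolerance = 1e-9)
  }
})

test_that("wc_fst agrees with the brute-force variance-components oracle", {
  # identical allele-frequency populations: theta <= 0
  blk <- matrix(c(0L, 1L, 1L, 2L, 0L, 1L, 1L, 2L), 4, 2)
  g_eq <- toy_genotypes(rbind(blk, blk), rep(c("A", "B"), each = 4))
  expect_lte(wc_fst(g_eq, "A", "B")$theta, 1e-12)
  # fixed difference gives theta = 1
  g_fx <- toy_genotypes(matrix(c(0L, 0L, 0L, 2L, 2L, 2L), 6, 2),
                        rep(c("A", "B"), each = 3))
  expect_equal(wc_fst(g_fx, "A", "B")$theta, 1)
  # random instances, <= 6 samples, <= 5 sites, with missing data
  set.seed(13)
  for (i in 1:40) {
    nA <- sample(2:3, 1); nB <- sample(2:3, 1)
    S <- sample(1:5, 1)
    g <- random_genotypes(c(A = nA, B = nB), n_sites = S, miss = 0.15)
    ga <- g$geno[g$pops == "A", , drop = FALSE]
    gb <- g$geno[g$pops == "B", , drop = FALSE]
    oracle <- wc_fst_oracle(ga, gb)
    ours <- wc_fst(g, "A", "B")$theta
    if (is.finite(oracle)) expect_equal(ours, oracle, tolerance = 1e-12)
  }
})

test_that("permutation p-values behave and are uniform under the null", {
  g_fx <- toy_genotypes(matrix(c(rep(0L, 12), rep(2L, 12)), 8, 3),
                        rep(c("A", "B"), each = 4))
  w <- wc_fst(g_fx, "A", "B", n_perm = 99, seed = 2)
  expect_lt(w$p_value, 0.05)
  set.seed(17)
  pvals <- replicate(40, {
    g <- random_genotypes(c(A = 4, B = 4), n_sites = 6)
    wc_fst(g, "A", "B", n_perm = 60, seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 1e-3)
})

test_that("dxy matches hand computation and self-dxy equals pi", {
  # identical fixed populations
  g0 <- toy_genotypes(matrix(2L, 4, 1), rep(c("A", "B"), each = 2))
  expect_equal(dxy(g0, "A", "B", total_length = 1), 0)
  # opposite fixed alleles at the only site, length 1
  g1 <- toy_genotypes(matrix(c(0L, 0L, 2L, 2L), 4, 1),
                      rep(c("A", "B"), each = 2))
  expect_equal(dxy(g1, "A", "B", total_length = 1), 1)
  # pA = 0.5, pB = 0.25, length 10 -> 0.05
  g2 <- toy_genotypes(matrix(c(1L, 1L, 1L, 0L), 4, 1),
                      rep(c("A", "B"), each = 2))
  expect_equal(dxy(g2, "A", "B", total_length = 10), 0.05)
  # a population against itself equals its pi over the same denominator
  set.seed(23)
  g3 <- random_genotypes(c(A = 5), n_sites = 6)
  pi_a <- diversity_stats(g3, invariant_sites_per_locus = 10)$pi
  expect_equal(dxy(g3, "A", "A", total_length = 6 * 10 + 6), pi_a,
               tolerance = 1e-12)
})

test_that("pairwise matrices are symmetric with empty diagonals", {
  set.seed(29)
  g <- random_genotypes(c(A = 4, B = 4, C = 4), n_sites = 10)
  ps <- pairwise_stats(g, n_perm = 20, seed = 1)
  expect_true(isSymmetric(ps$fst))
  expect_true(isSymmetric(ps$dxy))
  expect_true(all(is.na(diag(ps$fst))))
  expect_true(all(ps$fst[upper.tri(ps$fst)] <= 1))
})

test_that("windowed scan flags exactly the planted outlier window", {
  # 12 windows x 6 SNPs; one window carries a strong fixed difference
  set.seed(31)
  n_win <- 12; snps <- 6
  pops <- rep(c("A", "B"), each = 6)
  cols <- list()
  for (w in seq_len(n_win)) for (s in seq_len(snps)) {
    if (w == 5) cols[[length(cols) + 1]] <- c(rep(0L, 6), rep(2L, 6))
    else {
      x <- sample(0:2, 12, replace = TRUE)
      cols[[length(cols) + 1]] <- x
    }
  }
  geno <- do.call(cbind, cols)
  pos <- as.integer(rep((seq_len(n_win) - 1) * 1e6, each = snps) +
                      seq_len(snps) * 1000)
  g <- toy_genotypes(geno, pops, pos = pos,
                     locus = paste0("L", seq_len(n_win * snps)))
  scan <- window_fst_scan(g, "A", "B", window_bp = 1e6, min_snps = 5)
  expect_equal(nrow(scan), n_win)
  expect_equal(which(scan$outlier), 5L)
  # all-equal scan yields zero outliers (SD = 0)
  same <- do.call(cbind, rep(list(c(rep(0L, 6), rep(2L, 6))), 18))
  g2 <- toy_genotypes(same, pops,
                      pos = as.integer(rep((0:5) * 1e6, each = 3) +
                                         rep(1:3, 6) * 100),
                      locus = paste0("L", 1:18))
  scan2 <- window_fst_scan(g2, "A", "B", min_snps = 3)
  expect_false(any(scan2$outlier))
  # windows below min_snps are excluded
  expect_true(all(scan$n_snps >= 5))
})

test_that("PCA separates clusters and conserves variance", {
  set.seed(37)
  # two fixed-difference clusters
  block <- function(v, n, S) matrix(rep(v, n * S), n, S)
  geno <- rbind(block(0L, 5, 8), block(2L, 5, 8))
  noise <- matrix(sample(0:2, 10 * 4, replace = TRUE), 10, 4)
  g <- toy_genotypes(cbind(geno, noise), rep(c("A", "B"), each = 5))
  p <- pca_with_snp_correlation(g, n_components = 2)
  expect_true(max(p$scores[1:5, 1]) < min(p$scores[6:10, 1]) ||
                min(p$scores[1:5, 1]) > max(p$scores[6:10, 1]))
  expect_gt(min(p$snp_correlation[1:8, 1]), 0.99)
  # eigenvalues sum to the total variance of the scaled matrix
  X <- g$geno
  pm <- colMeans(X) / 2
  keep <- p$kept
  Z <- sweep(sweep(X[, keep], 2, 2 * pm[keep]), 2,
             sqrt(2 * pm[keep] * (1 - pm[keep])), "/")
  expect_equal(sum(p$sdev^2), sum(apply(Z, 2, stats::var)),
               tolerance = 1e-8)
  # unstructured genotypes: no dominant component
  g2 <- toy_genotypes(matrix(sample(0:2, 40 * 30, replace = TRUE), 40, 30),
                      rep("A", 40))
  p2 <- pca_with_snp_correlation(g2, n_components = 3)
  expect_lt(p2$explained[1], 0.25)
})
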