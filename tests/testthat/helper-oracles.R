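# Shared fixtures and independent brute-force oracles.

# Build a genotype_matrix from a plain matrix (samples x sites).
toy_genotypes <- function(geno, pops, chrom = NULL, pos = NULL,
                          locus = NULL, depth = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); S <- ncol(geno)
  ids <- paste0(pops, "_", stats::ave(seq_len(n), pops, FUN = seq_along))
  sites <- data.frame(
    chrom = chrom %||% rep("chr1", S),
    pos = pos %||% (seq_len(S) * 100L),
    locus = locus %||% paste0("L", seq_len(S)),
    ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_matrix(geno, ids, stats::setNames(pops, ids), sites, depth = depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_genotypes <- function(n_per_pop = c(A = 3, B = 3), n_sites = 4,
                             miss = 0) {
  pops <- rep(names(n_per_pop), n_per_pop)
  n <- length(pops)
  geno <- matrix(sample(0:2, n * n_sites, replace = TRUE), n, n_sites)
  if (miss > 0) geno[runif(n * n_sites) < miss] <- NA
  # ensure every site has at least one genotyped sample per population
  for (s in seq_len(n_sites)) for (p in unique(pops)) {
    rows <- which(pops == p)
    if (all(is.na(geno[rows, s]))) geno[rows[1], s] <- 1L
  }
  toy_genotypes(geno, pops)
}

# Direct per-site transcription of the Weir & Cockerham (1984) two-population
# variance components, a/b/c, combined as a ratio of sums.
wc_fst_oracle <- function(ga, gb) {
  S <- ncol(ga)
  A <- B <- C <- 0
  r <- 2
  for (s in seq_len(S)) {
    x1 <- ga[, s][!is.na(ga[, s])]
    x2 <- gb[, s][!is.na(gb[, s])]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 1 || n2 < 1 || n1 + n2 <= 2) next
    p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (!all(is.finite(c(a, b, cc)))) next
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}

# Exhaustive rarefaction: expected allele count over all C(N, k) subsets of
# the sampled genes (alleles coded 0/1, `alt` copies of allele 1).
ar_enumeration_oracle <- function(alt, N, k) {
  genes <- c(rep(1L, alt), rep(0L, N - alt))
  subsets <- utils::combn(N, k)
  mean(apply(subsets, 2, function(ix) length(unique(genes[ix]))))
}

# Exhaustive hypergeometric projection of a 1-D spectrum entry: expected
# subsample allele-count distribution over all C(n, k) subsets.
project_enumeration_oracle <- function(d, n, k) {
  genes <- c(rep(1L, d), rep(0L, n - d))
  subsets <- utils::combn(n, k)
  counts <- apply(subsets, 2, function(ix) sum(genes[ix]))
  tabulate(counts + 1L, nbins = k + 1) / ncol(subsets)
}

# Exact HWE test by full enumeration of the conditional heterozygote-count
# distribution (independent transcription, no log-space tricks).
hwe_enumeration_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nb <- 2 * n_bb + n_ab
  nb <- min(nb, 2 * n - nb)
  if (nb == 0) return(1)
  hets <- seq(nb %% 2, nb, by = 2)
  pr <- vapply(hets, function(h) {
    naa <- n - (nb + h) / 2
    nbb <- (nb - h) / 2
    factorial(n) / (factorial(naa) * factorial(h) * factorial(nbb)) * 2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs + 1e-12])
}
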