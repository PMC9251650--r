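#' Weir & Cockerham F_ST between two populations
#'
#' Multi-locus Weir & Cockerham (1984) theta computed from the among- (a),
#' between-individual (b) and within-individual (c) variance components,
#' combined as a ratio of sums over sites (the "weighted" estimator):
#' `theta = sum(a) / sum(a + b + c)`.  Missing genotypes are dropped per
#' site (pairwise deletion).  Significance is assessed by permuting
#' individuals between the two populations.
#'
#' @param g a [genotype_matrix].
#' @param popA,popB population labels.
#' @param n_perm number of label permutations (0 = no test).
#' @param seed integer seed for the permutations.
#' @return list with `theta`, `p_value` (fraction of permuted estimates
#'   greater than or equal to the observed; NA when `n_perm = 0`), `n_perm`
#'   and the summed components `a`, `b`, `c`.
#' @export
wc_fst <- function(g, popA, popB, n_perm = 0, seed = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  ga <- g$geno[g$pops == popA, , drop = FALSE]
  gb <- g$geno[g$pops == popB, , drop = FALSE]
  if (nrow(ga) < 2 || nrow(gb) < 2)
    stop("both populations need at least two diploids")
  obs <- wc_components(ga, gb)
  theta <- if (obs$denom > 0) obs$a / obs$denom else NA_real_
  p <- NA_real_
  if (n_perm > 0) {
    if (is.na(theta)) return(list(theta = NA_real_, p_value = 1,
                                  n_perm = n_perm, a = obs$a,
                                  b = obs$b, c = obs$c))
    pool <- rbind(ga, gb)
    nA <- nrow(ga)
    set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(nrow(pool))
      r <- wc_components(pool[idx[seq_len(nA)], , drop = FALSE],
                         pool[idx[-seq_len(nA)], , drop = FALSE])
      if (r$denom > 0) r$a / r$denom else -Inf
    }, numeric(1))
    p <- mean(perm >= theta)
  }
  list(theta = theta, p_value = p, n_perm = n_perm,
       a = obs$a, b = obs$b, c = obs$c)
}

# Summed W&C (1984) variance components for two populations over all sites;
# vectorized over sites.  Sites with fewer than one genotyped diploid in
# either population, or with nbar <= 1, contribute nothing.
wc_components <- function(ga, gb) {
  n1 <- colSums(!is.na(ga)); n2 <- colSums(!is.na(gb))
  p1 <- colSums(ga, na.rm = TRUE) / (2 * pmax(n1, 1))
  p2 <- colSums(gb, na.rm = TRUE) / (2 * pmax(n2, 1))
  h1 <- colSums(ga == 1L, na.rm = TRUE) / pmax(n1, 1)
  h2 <- colSums(gb == 1L, na.rm = TRUE) / pmax(n2, 1)
  r <- 2
  ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ok <- ok & is.finite(a) & is.finite(b) & is.finite(cc) & nc > 0
  list(a = sum(a[ok]), b = sum(b[ok]), c = sum(cc[ok]),
       denom = sum((a + b + cc)[ok]))
}

#' Pairwise F_ST / Dxy matrices over all populations
#'
#' @param g a [genotype_matrix].
#' @param n_perm permutations per pair for the F_ST significance test.
#' @param seed integer seed.
#' @param total_length per-site denominator length for Dxy (variant +
#'   invariant); defaults to `n_loci * 142 + n_sites`.
#' @return list of symmetric matrices `fst`, `p_value` and `dxy`.
#' @export
pairwise_stats <- function(g, n_perm = 0, seed = 1, total_length = NULL) {
  pops <- unique(g$pops)
  k <- length(pops)
  fst <- pv <- dx <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    w <- wc_fst(g, pops[i], pops[j], n_perm = n_perm,
                seed = seed + i * 1000 + j)
    fst[i, j] <- fst[j, i] <- w$theta
    pv[i, j] <- pv[j, i] <- w$p_value
    d <- dxy(g, pops[i], pops[j], total_length = total_length)
    dx[i, j] <- dx[j, i] <- d
  }
  list(fst = fst, p_value = pv, dxy = dx)
}

#' Absolute divergence Dxy between two populations
#'
#' `Dxy = sum_sites [pA (1 - pB) + pB (1 - pA)] / total_length`, where the
#' length includes invariant sequence.  Comparing a population against
#' itself uses the unbiased within-population average pairwise difference
#' (`2p(1-p) * 2n/(2n-1)` per site), so self-Dxy equals the population's
#' nucleotide diversity over the same denominator.
#'
#' @inheritParams wc_fst
#' @param total_length denominator length in bp; defaults to
#'   `n_loci * 142 + n_sites`.
#' @export
dxy <- function(g, popA, popB, total_length = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(total_length))
    total_length <- length(unique(g$sites$locus)) * 142 + ncol(g$geno)
  ac <- allele_counts(g, pops = unique(c(popA, popB)))
  pA <- ac$freq[popA, ]
  if (identical(popA, popB)) {
    n <- ac$n[popA, ]
    ok <- !is.na(pA) & n > 1
    return(sum(2 * pA[ok] * (1 - pA[ok]) * n[ok] / (n[ok] - 1)) /
             total_length)
  }
  pB <- ac$freq[popB, ]
  ok <- !is.na(pA) & !is.na(pB)
  sum(pA[ok] * (1 - pB[ok]) + pB[ok] * (1 - pA[ok])) / total_length
}

#' Windowed F_ST scan with outlier flags
#'
#' Splits each chromosome into fixed-width windows (0-based half-open
#' internally; reported as 1-based inclusive start/end), computes the
#' weighted Weir & Cockerham theta per window, drops windows with fewer
#' than `min_snps` SNPs, and flags windows at or above `mean + 3 SD` of the
#' retained-window estimates (no outliers are called when the SD is zero).
#' Negative window estimates are reported as-is.
#'
#' @inheritParams wc_fst
#' @param window_bp window width in bp.
#' @param min_snps minimum SNPs per retained window.
#' @param n_sd outlier threshold in standard deviations.
#' @return data.frame: `chrom`, `start`, `end`, `n_snps`, `fst`, `outlier`,
#'   with the scan mean and SD as attributes.
#' @export
window_fst_scan <- function(g, popA, popB, window_bp = 1e6, min_snps = 5,
                            n_sd = 3) {
  stopifnot(inherits(g, "genotype_matrix"))
  ga <- g$geno[g$pops == popA, , drop = FALSE]
  gb <- g$geno[g$pops == popB, , drop = FALSE]
  win <- floor((g$sites$pos - 1) / window_bp)
  key <- paste(g$sites$chrom, win, sep = "\r")
  rows <- split(seq_len(ncol(g$geno)), key)
  out <- lapply(rows, function(idx) {
    comp <- wc_components(ga[, idx, drop = FALSE], gb[, idx, drop = FALSE])
    data.frame(chrom = g$sites$chrom[idx[1]],
               start = win[idx[1]] * window_bp + 1,
               end = (win[idx[1]] + 1) * window_bp,
               n_snps = length(idx),
               fst = if (comp$denom > 0) comp$a / comp$denom else NA_real_)
  })
  scan <- do.call(rbind, out)
  scan <- scan[order(scan$chrom, scan$start), , drop = FALSE]
  scan <- scan[scan$n_snps >= min_snps & !is.na(scan$fst), , drop = FALSE]
  rownames(scan) <- NULL
  mu <- mean(scan$fst); sdev <- stats::sd(scan$fst)
  scan$outlier <- if (nrow(scan) && isTRUE(sdev > 0))
    scan$fst >= mu + n_sd * sdev else rep(FALSE, nrow(scan))
  attr(scan, "mean") <- mu
  attr(scan, "sd") <- sdev
  scan
}
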