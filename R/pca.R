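#' PCA of genotypes with per-SNP eigenvector correlations
#'
#' Runs a principal component analysis on the allele-frequency-centred and
#' scaled genotype matrix (genotype codes centred by `2p` and scaled by
#' `sqrt(2p(1-p))`; missing calls mean-imputed per SNP; zero-variance SNPs
#' dropped) and, to locate the genomic signal behind each axis, the Pearson
#' correlation between every SNP genotype and the sample scores of each
#' component.  A genome-wide pattern of moderate correlations indicates
#' drift-driven structure; isolated blocks of high correlation indicate
#' localized (e.g. inversion-like) signal.
#'
#' @param g a [genotype_matrix].
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `explained`
#'   (variance fractions), `snp_correlation` (|r|, SNPs x components; NA
#'   for dropped SNPs), `kept` (logical mask of SNPs used) and `sdev`.
#' @export
pca_with_snp_correlation <- function(g, n_components = 2) {
  stopifnot(inherits(g, "genotype_matrix"))
  X <- g$geno
  if (nrow(X) < 2 || ncol(X) < 2) stop("need at least 2 samples and 2 SNPs")
  p <- colMeans(X, na.rm = TRUE) / 2
  for (j in seq_len(ncol(X))) {
    m <- is.na(X[, j])
    if (any(m)) X[m, j] <- 2 * p[j]
  }
  keep <- apply(X, 2, stats::var) > 0
  Z <- sweep(X[, keep, drop = FALSE], 2, 2 * p[keep], `-`)
  Z <- sweep(Z, 2, sqrt(2 * p[keep] * (1 - p[keep])), `/`)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  corr <- matrix(NA_real_, ncol(g$geno), k,
                 dimnames = list(NULL, colnames(scores)))
  corr[keep, ] <- abs(stats::cor(X[, keep, drop = FALSE], scores))
  list(scores = scores,
       explained = pc$sdev^2 / sum(pc$sdev^2),
       snp_correlation = corr,
       kept = keep,
       sdev = pc$sdev)
}
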