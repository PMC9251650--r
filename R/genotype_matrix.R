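#' Diploid biallelic genotype matrix
#'
#' The central data container: per-sample, per-site genotype codes counting
#' alternate alleles (0, 1, 2, `NA` for missing), a population label per
#' sample, per-site records (chromosome, 1-based position, locus id, ref and
#' alt alleles) and an optional read-depth matrix of the same shape.
#'
#' @param geno integer matrix, samples x sites, values in `{0, 1, 2, NA}`.
#' @param sample_ids character vector of sample names.
#' @param pops named character vector mapping every sample to a population.
#' @param sites data.frame with columns `chrom`, `pos`, `locus`, `ref`,
#'   `alt`; positions must be strictly increasing within a chromosome.
#' @param depth optional numeric matrix, samples x sites.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sample_ids, pops, sites, depth = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(nrow(geno) == length(sample_ids),
            nrow(sites) == ncol(geno),
            all(c("chrom", "pos", "locus") %in% names(sites)))
  bad <- setdiff(unique(geno[!is.na(geno)]), 0:2)
  if (length(bad)) stop("genotype codes outside {0, 1, 2, NA}: ",
                        paste(bad, collapse = ", "))
  if (!all(sample_ids %in% names(pops)))
    stop("samples without a population label: ",
         paste(setdiff(sample_ids, names(pops)), collapse = ", "))
  ord <- order(sites$chrom, sites$pos)
  if (any(diff(ord) != 1)) {
    sites <- sites[ord, , drop = FALSE]
    rownames(sites) <- NULL
    geno <- geno[, ord, drop = FALSE]
    if (!is.null(depth)) depth <- depth[, ord, drop = FALSE]
  }
  if (any(unlist(tapply(sites$pos, sites$chrom, function(p) diff(p) <= 0))))
    stop("positions must be strictly increasing within a chromosome")
  rownames(geno) <- sample_ids
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(identical(dim(depth), dim(geno)))
    rownames(depth) <- sample_ids
  }
  structure(list(geno = geno, depth = depth,
                 sample_ids = sample_ids,
                 pops = pops[sample_ids],
                 sites = sites),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples, %d sites, %d populations%s\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$pops)),
              if (is.null(x$depth)) "" else ", with depth"))
  tab <- table(x$pops)
  cat("  ", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Subset a genotype matrix by samples and/or sites
#'
#' @param g a [genotype_matrix].
#' @param samples sample names or indices to keep.
#' @param sites site indices (or logical mask) to keep.
#' @export
subset_genotypes <- function(g, samples = NULL, sites = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(samples)) samples <- g$sample_ids
  if (is.character(samples)) samples <- match(samples, g$sample_ids)
  if (is.null(sites)) sites <- seq_len(ncol(g$geno))
  genotype_matrix(g$geno[samples, sites, drop = FALSE],
                  g$sample_ids[samples], g$pops,
                  g$sites[sites, , drop = FALSE],
                  depth = if (!is.null(g$depth))
                    g$depth[samples, sites, drop = FALSE])
}

#' Per-population allele counts and frequencies
#'
#' @param g a [genotype_matrix].
#' @param pops populations to include (default all).
#' @return list with matrices `alt` (alt allele count), `n` (genotyped
#'   genes), both populations x sites, and `freq = alt / n`.
#' @export
allele_counts <- function(g, pops = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(pops)) pops <- unique(g$pops)
  S <- ncol(g$geno)
  per_pop <- function(f) {
    out <- vapply(pops, function(p)
      f(g$geno[g$pops == p, , drop = FALSE]), numeric(S))
    t(matrix(out, nrow = S, dimnames = list(NULL, pops)))
  }
  alt <- per_pop(function(x) colSums(x, na.rm = TRUE))
  n <- per_pop(function(x) 2 * colSums(!is.na(x)))
  list(alt = alt, n = n, freq = ifelse(n > 0, alt / n, NA_real_))
}
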