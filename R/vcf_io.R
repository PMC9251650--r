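#' Read a VCF and population map into a genotype matrix
#'
#' Decodes diploid GT fields of a VCF 4.x file (via \pkg{vcfR}) into
#' alt-allele counts, preserving missing calls, and attaches per-genotype
#' read depths from the DP format field when present.  Sites that are not
#' biallelic SNPs are skipped with a message.  Locus ids are taken from the
#' ID column (the part before the first `:` or `_`); sites with `.` ids get
#' one locus per site.
#'
#' @param path VCF file (plain or gzipped).
#' @param popmap path to a two-column whitespace-separated file (sample,
#'   population), or a named character vector.
#' @return a [genotype_matrix].
#' @export
read_vcf <- function(path, popmap) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  ok <- !is.na(alt) & !grepl(",", alt) & nchar(alt) == 1 & nchar(ref) == 1
  n_skip <- sum(!ok)
  if (n_skip) message("skipped ", n_skip, " non-biallelic site(s)")
  gt <- vcfR::extract.gt(v, element = "GT")[ok, , drop = FALSE]
  samples <- colnames(gt)
  pops <- if (is.character(popmap) && length(popmap) == 1 && file.exists(popmap))
    read_popmap(popmap) else popmap
  missing_pop <- setdiff(samples, names(pops))
  if (length(missing_pop))
    stop("sample(s) in VCF absent from popmap: ",
         paste(missing_pop, collapse = ", "))
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  known <- !is.na(gt) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  code[known] <- (a1[known] == "1") + (a2[known] == "1")
  depth <- NULL
  fmt <- v@gt[ok, 1, drop = TRUE]
  if (all(grepl("DP", fmt))) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth <- t(dp[ok, , drop = FALSE])
  }
  ids <- fix[ok, "ID"]
  locus <- sub("[:_].*$", "", ids)
  locus[is.na(ids) | ids == "."] <-
    paste0("s", seq_len(sum(is.na(ids) | ids == ".")))
  sites <- data.frame(chrom = fix[ok, "CHROM"],
                      pos = as.integer(fix[ok, "POS"]),
                      locus = locus,
                      ref = ref[ok], alt = alt[ok],
                      stringsAsFactors = FALSE)
  genotype_matrix(t(code), sample_ids = samples, pops = pops,
                  sites = sites, depth = depth)
}

#' @rdname read_vcf
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample", "pop"))
  stats::setNames(tab$pop, tab$sample)
}

#' Write a genotype matrix as VCF 4.2 plus a population map
#'
#' Emits unphased GT (and DP when depths are present) records; site ids are
#' `"<locus>:<i>"` so locus membership round-trips through [read_vcf()].
#'
#' @param g a [genotype_matrix].
#' @param path output VCF path.
#' @param popmap_path optional path for the two-column population map.
#' @export
write_vcf <- function(g, path, popmap_path = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$geno + 1L],
                   nrow = nrow(g$geno))
  gt_str[is.na(g$geno)] <- "./."
  fmt <- "GT"
  if (!is.null(g$depth)) {
    dp <- ifelse(is.na(g$depth), ".", format(g$depth, trim = TRUE))
    gt_str <- matrix(paste0(gt_str, ":", dp), nrow = nrow(gt_str))
    fmt <- "GT:DP"
  }
  within <- stats::ave(seq_len(nrow(g$sites)), g$sites$locus, FUN = seq_along)
  body <- paste(g$sites$chrom, g$sites$pos,
                paste0(g$sites$locus, ":", within),
                g$sites$ref, g$sites$alt, ".", "PASS", ".", fmt,
                apply(gt_str, 2, paste, collapse = "\t"),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=postglacial",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(g$depth))
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$sample_ids), collapse = "\t"))
  writeLines(c(header, body), path)
  if (!is.null(popmap_path))
    writeLines(paste(g$sample_ids, g$pops), popmap_path)
  invisible(path)
}
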