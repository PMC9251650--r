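#' Multidimensional site frequency spectrum
#'
#' An `msfs` stores the joint (across demes) minor-allele site frequency
#' spectrum: for each polymorphic entry, the per-deme minor-allele counts
#' and the number (possibly fractional, after projection) of sites observed
#' at that entry, together with a monomorphic-site count that anchors the
#' absolute mutational scale of the spectrum.
#'
#' Folding is to the globally minor allele: every entry satisfies
#' `sum(idx) <= sum(sample_sizes) / 2`; when a site is exactly at half
#' frequency the tie is broken deterministically by keeping the
#' lexicographically smaller index vector.
#'
#' @param idx integer matrix (entries x demes) of per-deme allele counts.
#' @param counts numeric vector of site counts per entry.
#' @param sample_sizes named integer vector of sampled genes per deme.
#' @param monomorphic number of monomorphic sites.
#' @param folded logical flag.
#' @return an object of class `msfs`.
#' @export
msfs <- function(idx, counts, sample_sizes, monomorphic = 0, folded = TRUE) {
  idx <- as.matrix(idx)
  storage.mode(idx) <- "integer"
  stopifnot(nrow(idx) == length(counts),
            ncol(idx) == length(sample_sizes),
            !is.null(names(sample_sizes)),
            all(counts >= 0), monomorphic >= 0)
  if (any(idx < 0) || any(t(idx) > sample_sizes))
    stop("entry indices must lie in [0, sample_size] per deme")
  sample_sizes <- stats::setNames(as.integer(sample_sizes),
                                  names(sample_sizes))
  colnames(idx) <- names(sample_sizes)
  structure(list(idx = idx, counts = as.numeric(counts),
                 sample_sizes = sample_sizes,
                 monomorphic = monomorphic, folded = folded),
            class = "msfs")
}

#' @export
print.msfs <- function(x, ...) {
  cat(sprintf("%s MSFS over %d deme(s) [%s]: %d entries, %.6g segregating, %.6g monomorphic\n",
              if (x$folded) "folded" else "unfolded",
              ncol(x$idx),
              paste(names(x$sample_sizes), x$sample_sizes, sep = "=",
                    collapse = ", "),
              nrow(x$idx), sum(x$counts), x$monomorphic))
  invisible(x)
}

msfs_keys <- function(idx, sizes) {
  radix <- cumprod(c(1, utils::head(sizes + 1, -1)))
  as.vector(idx %*% radix)
}

# Fold index rows to the globally minor allele and aggregate equal entries.
msfs_aggregate <- function(idx, counts, sizes, fold = TRUE) {
  idx <- as.matrix(idx)
  if (fold && nrow(idx)) {
    n <- sum(sizes)
    tot <- rowSums(idx)
    comp <- sweep(-idx, 2, sizes, `+`)
    flip <- tot > n / 2
    tie <- which(tot * 2 == n)
    if (length(tie)) {
      # keep the lexicographically smaller of (idx, complement)
      for (i in tie) {
        a <- idx[i, ]; b <- comp[i, ]
        d <- which(a != b)
        if (length(d) && a[d[1]] > b[d[1]]) flip[i] <- TRUE
      }
    }
    idx[flip, ] <- comp[flip, ]
  }
  key <- msfs_keys(idx, sizes)
  agg <- rowsum(as.numeric(counts), group = key)
  ord <- match(as.numeric(rownames(agg)), key)
  msfs(idx[ord, , drop = FALSE], as.vector(agg), sizes, folded = fold)
}

#' Build an MSFS from observed genotypes
#'
#' Each fully genotyped SNP increments one entry of the spectrum at its
#' per-deme minor-allele-count index.  Missing genotypes are not allowed:
#' down-sample first with [downsample_genotypes()].  The monomorphic entry
#' is initialized to zero; set it with [correct_monomorphic()].
#'
#' @param g a [genotype_matrix].
#' @param demes character vector: populations to include, in deme order.
#' @return an [msfs].
#' @export
msfs_from_genotypes <- function(g, demes) {
  stopifnot(inherits(g, "genotype_matrix"))
  miss <- setdiff(demes, unique(g$pops))
  if (length(miss)) stop("populations absent from data: ",
                         paste(miss, collapse = ", "))
  rows <- lapply(demes, function(d) which(g$pops == d))
  sub <- g$geno[unlist(rows), , drop = FALSE]
  bad <- which(colSums(is.na(sub)) > 0)
  if (length(bad))
    stop("missing genotypes at site(s) ", paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "",
         "; down-sample to fully genotyped individuals first")
  idx <- vapply(rows, function(r)
    colSums(g$geno[r, , drop = FALSE]), numeric(ncol(g$geno)))
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  sizes <- stats::setNames(2L * lengths(rows), demes)
  # sites monomorphic across the listed demes (possible when `demes` is a
  # subset of the data) belong to the monomorphic entry, not to a cell
  msfs_from_counts(idx, sizes, total_sites = nrow(idx))
}

#' Hypergeometric projection of an MSFS to a smaller sample size
#'
#' Each entry is redistributed over smaller per-deme indices with exact
#' hypergeometric weights (the expected spectrum of every subsample of `k`
#' genes per deme), then re-folded.  Mass projected onto the all-zero (or
#' all-fixed) cell is added to the monomorphic count, so total mass is
#' conserved.
#'
#' @param m an [msfs].
#' @param k genes per deme after projection; scalar or named vector.
#' @return the projected [msfs].
#' @export
project_msfs <- function(m, k) {
  stopifnot(inherits(m, "msfs"))
  sizes <- m$sample_sizes
  if (length(k) == 1) k <- stats::setNames(rep(k, length(sizes)), names(sizes))
  k <- k[names(sizes)]
  if (any(k > sizes)) stop("cannot project up: k exceeds a sample size")
  if (any(k < 1)) stop("k must be at least 1 per deme")
  idx <- m$idx; counts <- m$counts
  for (d in seq_along(sizes)) {
    n_d <- sizes[d]; k_d <- k[d]
    if (k_d == n_d) next
    # weight matrix W[j+1, i+1] = P(i of k | j of n) hypergeometric
    j <- 0:n_d
    W <- vapply(0:k_d, function(i)
      exp(lchoose(j, i) + lchoose(n_d - j, k_d - i) - lchoose(n_d, k_d)),
      numeric(n_d + 1))
    new_idx <- vector("list", k_d + 1)
    new_cnt <- vector("list", k_d + 1)
    for (i in 0:k_d) {
      w <- W[idx[, d] + 1, i + 1]
      keep <- w > 0
      ni <- idx[keep, , drop = FALSE]
      ni[, d] <- i
      new_idx[[i + 1]] <- ni
      new_cnt[[i + 1]] <- counts[keep] * w[keep]
    }
    idx <- do.call(rbind, new_idx)
    counts <- unlist(new_cnt)
    # aggregate on interim sizes to bound growth
    interim <- sizes; interim[seq_len(d)] <- k[seq_len(d)]
    key <- msfs_keys(idx, interim)
    agg <- rowsum(counts, group = key)
    ord <- match(as.numeric(rownames(agg)), key)
    idx <- idx[ord, , drop = FALSE]
    counts <- as.vector(agg)
  }
  tot <- rowSums(idx)
  mono_mass <- sum(counts[tot == 0 | tot == sum(k)])
  poly <- tot > 0 & tot < sum(k)
  out <- msfs_aggregate(idx[poly, , drop = FALSE], counts[poly], k,
                        fold = m$folded)
  out$monomorphic <- m$monomorphic + mono_mass
  out
}

#' Set the monomorphic entry from a total sequence length
#'
#' Divergence times and sizes are identifiable on an absolute scale only if
#' the spectrum records how many sites were surveyed in total; this sets
#' `monomorphic = total_sites - polymorphic`.
#'
#' @param m an [msfs].
#' @param total_sites total surveyed sites (variant + invariant), typically
#'   `n_loci * locus_length`.
#' @export
correct_monomorphic <- function(m, total_sites) {
  stopifnot(inherits(m, "msfs"))
  poly <- sum(m$counts)
  if (total_sites < poly)
    stop("total_sites (", total_sites, ") smaller than polymorphic count (",
         poly, ")")
  m$monomorphic <- total_sites - poly
  m
}

#' Read and write the flat MSFS text format
#'
#' The native format is line-oriented: a header of per-deme sample sizes,
#' the monomorphic count and the folded flag, then one `i1,i2,...<TAB>count`
#' line per entry.  `read_msfs()` also accepts dadi/fastsimcoal-style flat
#' 1-D and 2-D spectra (first non-comment line `n1 [n2]`, second line the
#' row-major cell values); cell `[0, ..., 0]` is taken as the monomorphic
#' count.
#'
#' @param m an [msfs]; `path` a file path.
#' @export
write_msfs <- function(m, path) {
  stopifnot(inherits(m, "msfs"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste("#msfs", if (m$folded) "folded" else "unfolded"),
    paste("sizes:", paste(names(m$sample_sizes), m$sample_sizes,
                          sep = "=", collapse = " ")),
    paste("monomorphic:", format(m$monomorphic, digits = 15))
  ), con)
  writeLines(paste0(apply(m$idx, 1, paste, collapse = ","), "\t",
                    format(m$counts, digits = 15, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_msfs
#' @export
read_msfs <- function(path) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "#msfs")) {
    folded <- grepl("(^| )folded", lines[1])
    sz <- strsplit(sub("^sizes:\\s*", "", lines[2]), "\\s+")[[1]]
    parts <- strsplit(sz, "=")
    sizes <- stats::setNames(as.integer(vapply(parts, `[`, "", 2)),
                             vapply(parts, `[`, "", 1))
    mono <- as.numeric(sub("^monomorphic:\\s*", "", lines[3]))
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    if (!length(body))
      return(msfs(matrix(0L, 0, length(sizes)), numeric(0), sizes,
                  monomorphic = mono, folded = folded))
    split2 <- strsplit(body, "\t")
    idx <- do.call(rbind, lapply(split2, function(x)
      as.integer(strsplit(x[1], ",")[[1]])))
    counts <- as.numeric(vapply(split2, `[`, "", 2))
    return(msfs(idx, counts, sizes, monomorphic = mono, folded = folded))
  }
  # dadi-style flat spectrum
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  dims <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  dims <- dims[!is.na(dims)]
  vals <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  sizes <- stats::setNames(dims - 1L, paste0("deme", seq_along(dims)))
  grid <- as.matrix(expand.grid(lapply(rev(dims), function(d) 0:(d - 1))))
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]  # row-major order
  colnames(grid) <- names(sizes)
  tot <- rowSums(grid)
  mono <- sum(vals[tot == 0 | tot == sum(sizes)])
  poly <- tot > 0 & tot < sum(sizes) & vals > 0
  out <- msfs_aggregate(grid[poly, , drop = FALSE], vals[poly], sizes,
                        fold = TRUE)
  out$monomorphic <- mono
  out
}

# Align a simulated spectrum to an observed one by entry key and return the
# probability of each observed entry (plus the monomorphic probability).
msfs_match_probs <- function(observed, simulated, total_sim_sites) {
  stopifnot(identical(unname(observed$sample_sizes),
                      unname(simulated$sample_sizes)))
  key_o <- msfs_keys(observed$idx, observed$sample_sizes)
  key_s <- msfs_keys(simulated$idx, simulated$sample_sizes)
  hit <- match(key_o, key_s)
  p <- ifelse(is.na(hit), 0, simulated$counts[hit]) / total_sim_sites
  list(p_entries = p, p_mono = simulated$monomorphic / total_sim_sites)
}
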