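#' Simulate coalescent genealogies, loci and site frequency spectra
#'
#' `simulate_genealogy()` draws one coalescent genealogy for a sample from a
#' multi-deme demographic model and returns it as an [ape::phylo] tree with
#' branch lengths in generations.  `simulate_sites()` is the bulk interface:
#' it simulates many independent non-recombining loci under the
#' infinite-sites model and returns the derived-allele count of every
#' segregating site in every deme.  `simulate_msfs()` aggregates such sites
#' into a folded multidimensional site frequency spectrum, and
#' `simulate_genotypes()` pairs sampled genes into diploid genotypes.
#'
#' @param model a validated [demographic_model()].
#' @param samples named vector: diploid individuals sampled per deme (demes
#'   absent from `samples` are unsampled ghost demes).
#' @param genes named vector of sampled gene copies (haploid chromosomes)
#'   per deme; used instead of `samples` when odd gene counts are needed.
#' @param seed integer seed.  Each locus derives its own RNG substream from
#'   `(seed, locus index)`, so results for locus `i` do not depend on how
#'   many loci are requested.
#' @return `simulate_genealogy()`: a `phylo` with tip labels
#'   `<deme>_<i>`; `simulate_sites()`: list with `counts` (sites x demes
#'   derived-allele counts), `locus`, `tmrca`, `tlen` and (if
#'   `carriers = TRUE`) a 0/1 sites x genes matrix; `simulate_msfs()`: an
#'   [msfs] object; `simulate_genotypes()`: a [genotype_matrix].
#' @examples
#' m <- demographic_model(c(A = 1000), locus_length = 100)
#' tr <- simulate_genealogy(m, samples = c(A = 3), seed = 1)
#' sf <- simulate_msfs(m, samples = c(A = 4), n_loci = 100, seed = 1)
#' @export
simulate_genealogy <- function(model, samples, seed) {
  model <- validate_model(model)
  genes <- sample_genes(model, samples = samples)
  res <- .sim_coalescent_cpp(length(model$demes), unname(model$sizes),
                             encode_events(model), genes,
                             0.0, 1L, as.double(seed), 2L)
  history_to_phylo(res$history, genes, model$demes)
}

#' @rdname simulate_genealogy
#' @param n_loci number of independent loci.
#' @param mu_len expected mutations per generation per locus; defaults to
#'   `mutation_rate * locus_length` of the model.
#' @param carriers also return the per-gene carrier matrix.
#' @export
simulate_sites <- function(model, samples = NULL, genes = NULL, n_loci, seed,
                           mu_len = NULL, carriers = FALSE) {
  model <- validate_model(model)
  g <- sample_genes(model, samples = samples, genes = genes)
  if (is.null(mu_len)) mu_len <- model$mutation_rate * model$locus_length
  res <- .sim_coalescent_cpp(length(model$demes), unname(model$sizes),
                             encode_events(model), g,
                             mu_len, as.integer(n_loci), as.double(seed),
                             if (carriers) 1L else 0L)
  colnames(res$counts) <- model$demes
  res$genes <- g
  res
}

#' @rdname simulate_genealogy
#' @export
simulate_msfs <- function(model, samples = NULL, genes = NULL, n_loci, seed,
                          mu_len = NULL) {
  g <- sample_genes(model, samples = samples, genes = genes)
  sampled <- g > 0
  sim <- simulate_sites(model, genes = g, n_loci = n_loci, seed = seed,
                        mu_len = mu_len)
  msfs_from_counts(sim$counts[, sampled, drop = FALSE], g[sampled],
                   total_sites = as.integer(n_loci) * model$locus_length)
}

#' Fold per-site allele counts into an MSFS
#'
#' Aggregates a table of per-site, per-deme derived (or alternate) allele
#' counts -- e.g. from [simulate_sites()], possibly restricted to a subset
#' of demes to obtain a marginal spectrum -- into a folded [msfs].  Sites
#' monomorphic across the included demes are counted into the monomorphic
#' entry.
#'
#' @param counts sites x demes matrix of allele counts.
#' @param sizes named vector of sampled genes per deme (matching columns).
#' @param total_sites total surveyed sites (variant + invariant) for the
#'   monomorphic entry, typically `n_loci * locus_length`.
#' @return an [msfs].
#' @export
msfs_from_counts <- function(counts, sizes, total_sites) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(sizes), !is.null(names(sizes)))
  tot <- rowSums(counts)
  keep <- tot > 0 & tot < sum(sizes)
  m <- msfs_aggregate(counts[keep, , drop = FALSE], rep(1, sum(keep)),
                      sizes, fold = TRUE)
  m$monomorphic <- total_sites - sum(keep)
  if (m$monomorphic < 0) stop("total_sites smaller than segregating count")
  m
}

#' @rdname simulate_genealogy
#' @param chrom,pos optional site coordinates; by default loci are placed
#'   consecutively 1 kb apart on one pseudo-chromosome.
#' @export
simulate_genotypes <- function(model, samples, n_loci, seed, mu_len = NULL,
                               chrom = NULL, pos = NULL) {
  stopifnot(!is.null(names(samples)))
  sim <- simulate_sites(model, samples = samples, n_loci = n_loci,
                        seed = seed, mu_len = mu_len, carriers = TRUE)
  carr <- sim$carriers
  genes <- sim$genes
  n_dip <- sum(samples)
  geno <- carr[, seq(1, 2 * n_dip, by = 2), drop = FALSE] +
    carr[, seq(2, 2 * n_dip, by = 2), drop = FALSE]
  geno <- t(geno)  # samples x sites
  dip_per_deme <- genes %/% 2
  pops <- rep(model$demes, dip_per_deme)
  ids <- unlist(lapply(model$demes[dip_per_deme > 0], function(d)
    paste0(d, "_", seq_len(dip_per_deme[match(d, model$demes)])))
  )
  if (is.null(chrom)) chrom <- rep("chr1", length(sim$locus))
  if (is.null(pos)) pos <- sim$locus * 1000L + stats::ave(
    seq_along(sim$locus), sim$locus, FUN = seq_along)
  sites <- data.frame(chrom = chrom, pos = as.integer(pos),
                      locus = sim$locus,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_matrix(geno, sample_ids = ids, pops = stats::setNames(pops, ids),
                  sites = sites)
}

#' Drop mutations on a fixed genealogy
#'
#' Places Poisson(`mu * L * branch length`) infinite-sites mutations on each
#' branch of a coalescent tree and reports, for every resulting segregating
#' site, which tips carry the derived allele.
#'
#' @param tree an ultrametric `phylo` with branch lengths in generations.
#' @param mu per-bp per-generation mutation rate.
#' @param L locus length in bp.
#' @param seed integer seed.
#' @return list with `carriers` (sites x tips 0/1 matrix) and `counts`
#'   (derived-allele count per site).
#' @export
simulate_locus <- function(tree, mu, L, seed) {
  stopifnot(inherits(tree, "phylo"))
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  nm <- stats::rpois(nrow(tree$edge), mu * L * tree$edge.length)
  rows <- list()
  for (i in which(nm > 0)) {
    node <- tree$edge[i, 2]
    tips <- tips_under(tree, node)
    v <- integer(n_tip); v[tips] <- 1L
    rows <- c(rows, rep(list(v), nm[i]))
  }
  carriers <- if (length(rows)) do.call(rbind, rows) else
    matrix(0L, 0, n_tip)
  colnames(carriers) <- tree$tip.label
  list(carriers = carriers, counts = rowSums(carriers))
}

tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_under, tree = tree))
}

sample_genes <- function(model, samples = NULL, genes = NULL) {
  D <- length(model$demes)
  if (is.null(genes)) {
    stopifnot(!is.null(samples), !is.null(names(samples)))
    genes <- 2L * as.integer(samples)
    names(genes) <- names(samples)
  }
  stopifnot(!is.null(names(genes)))
  unknown <- setdiff(names(genes), model$demes)
  if (length(unknown)) stop("sampled demes not in model: ",
                            paste(unknown, collapse = ", "))
  out <- integer(D)
  out[match(names(genes), model$demes)] <- as.integer(genes)
  names(out) <- model$demes
  if (sum(out) < 2) stop("need at least two sampled genes overall")
  out
}

history_to_phylo <- function(h, genes, demes) {
  n <- sum(genes)
  m <- nrow(h)                        # n - 1 coalescences
  node_time <- c(rep(0, n), h[, "time"])
  # engine ids are 0-based: leaves 0..n-1, internals n..2n-2 (root last).
  # ape wants tips 1..n, root n+1, then other internals.
  ape_id <- integer(2 * n - 1)
  ape_id[seq_len(n)] <- seq_len(n)
  internal <- (n + 1):(2 * n - 1)
  ape_id[2 * n - 1] <- n + 1          # root (last created)
  if (m > 1) ape_id[internal[-m]] <- (n + 2):(2 * n - 1)
  edge <- matrix(0L, 2 * (n - 1), 2)
  len <- numeric(2 * (n - 1))
  for (i in seq_len(m)) {
    p <- ape_id[h[i, "parent"] + 1]
    for (j in 1:2) {
      child <- h[i, j]
      edge[2 * (i - 1) + j, ] <- c(p, ape_id[child + 1])
      len[2 * (i - 1) + j] <- h[i, "time"] - node_time[child + 1]
    }
  }
  labels <- unlist(lapply(seq_along(demes), function(d)
    if (genes[d] > 0) paste0(demes[d], "_", seq_len(genes[d]))))
  tr <- structure(list(edge = edge, edge.length = len,
                       tip.label = labels, Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}
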