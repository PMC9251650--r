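#' Collapse an alignment into haplotypes
#'
#' Alignment columns containing a gap or IUPAC ambiguity in any sequence
#' are excluded alignment-wide before comparison (so sequences differing
#' only at an excluded site merge); identical sequences are then collapsed
#' into haplotypes with frequencies and per-population tallies.
#'
#' @param aln a character matrix (sequences x sites), an [ape::DNAbin]
#'   matrix, or the path to an aligned FASTA file.
#' @param pops optional named vector mapping sequence names to populations;
#'   by default the part of each name before the last `_` is used.
#' @param exclude_ambiguous drop columns with non-ACGT symbols.
#' @return a `haplotype_set`: `seqs` (haplotype x site character matrix,
#'   rows named H1, H2, ... in order of first appearance after canonical
#'   sequence sorting), `freq`, `pop_counts` and `members`.
#' @export
collapse_haplotypes <- function(aln, pops = NULL, exclude_ambiguous = TRUE) {
  if (is.character(aln) && length(aln) == 1 && file.exists(aln))
    aln <- ape::read.dna(aln, format = "fasta", as.character = TRUE,
                         as.matrix = TRUE)
  if (inherits(aln, "DNAbin"))
    aln <- as.character(as.matrix(aln))
  if (!is.matrix(aln) || nrow(aln) == 0) stop("empty or ragged alignment")
  aln <- toupper(aln)
  if (exclude_ambiguous) {
    keep <- apply(aln, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    aln <- aln[, keep, drop = FALSE]
  }
  seq_str <- apply(aln, 1, paste, collapse = "")
  if (is.null(pops)) {
    nm <- rownames(aln)
    if (is.null(nm)) nm <- paste0("seq", seq_len(nrow(aln)))
    pops <- stats::setNames(sub("_[^_]*$", "", nm), nm)
    rownames(aln) <- nm
  }
  uniq <- sort(unique(seq_str))       # canonical, order-independent
  # label haplotypes by decreasing frequency (ties by sequence) for
  # readable output
  freq <- vapply(uniq, function(s) sum(seq_str == s), numeric(1))
  ord <- order(-freq, uniq)
  uniq <- uniq[ord]; freq <- freq[ord]
  labels <- paste0("H", seq_along(uniq))
  members <- lapply(uniq, function(s) rownames(aln)[seq_str == s])
  pop_levels <- sort(unique(unname(pops[rownames(aln)])))
  pop_counts <- t(vapply(members, function(mm)
    table(factor(unname(pops[mm]), levels = pop_levels)),
    numeric(length(pop_levels))))
  rownames(pop_counts) <- labels
  seqs <- do.call(rbind, lapply(uniq, function(s)
    strsplit(s, "")[[1]]))
  rownames(seqs) <- labels
  structure(list(seqs = seqs, freq = stats::setNames(freq, labels),
                 pop_counts = pop_counts,
                 members = stats::setNames(members, labels)),
            class = "haplotype_set")
}

hamming_matrix <- function(seqs) {
  n <- nrow(seqs)
  d <- matrix(0L, n, n, dimnames = list(rownames(seqs), rownames(seqs)))
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- sum(seqs[i, ] != seqs[j, ])
  d
}

# epsilon-relaxed minimum spanning network: process distance classes in
# increasing order; within a class, an edge joins the network if its
# endpoints are not already connected by strictly smaller distances (or by
# classes within epsilon of the connecting distance).  Deterministic:
# classes and, within a class, edges are processed in lexicographic label
# order.
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2) return(data.frame(from = character(0), to = character(0),
                               steps = integer(0)))
  labs <- rownames(d)
  comp <- seq_len(n)
  edges <- list()
  classes <- sort(unique(d[upper.tri(d)]))
  for (dc in classes) {
    idx <- which(upper.tri(d) & d == dc, arr.ind = TRUE)
    idx <- idx[order(labs[idx[, 1]], labs[idx[, 2]]), , drop = FALSE]
    joined_pairs <- idx[comp[idx[, 1]] != comp[idx[, 2]], , drop = FALSE]
    if (nrow(joined_pairs) == 0) next
    for (r in seq_len(nrow(joined_pairs))) {
      i <- joined_pairs[r, 1]; j <- joined_pairs[r, 2]
      edges[[length(edges) + 1]] <- data.frame(
        from = labs[i], to = labs[j], steps = dc,
        stringsAsFactors = FALSE)
    }
    # merge components only after adding the whole class (union of MSTs)
    for (r in seq_len(nrow(joined_pairs))) {
      i <- joined_pairs[r, 1]; j <- joined_pairs[r, 2]
      ci <- comp[i]; cj <- comp[j]
      if (ci != cj) comp[comp == cj] <- ci
    }
    if (length(unique(comp)) == 1 && epsilon == 0) break
  }
  do.call(rbind, edges)
}

#' Median-joining haplotype network
#'
#' Builds the Bandelt-Forster-Roehl median-joining network: starting from
#' the epsilon-relaxed minimum spanning network on Hamming distances, the
#' algorithm repeatedly proposes, for triplets of mutually linked nodes,
#' the per-site majority consensus (median/Steiner) vector; medians that
#' shorten the local connection are added as inferred nodes and the network
#' is rebuilt, iterating to a fixpoint.  Median nodes that end up redundant
#' (on a path whose endpoints are at their summed distance) are pruned.
#'
#' @param h a `haplotype_set` from [collapse_haplotypes()] (>= 2
#'   haplotypes).
#' @param epsilon relaxation parameter of the spanning network (0 gives the
#'   strict union of minimum spanning trees).
#' @param max_iter safety cap on median-addition rounds.
#' @return an `mj_network`: `nodes` (label, freq, median flag), `edges`
#'   (from, to, steps).
#' @export
median_joining <- function(h, epsilon = 0, max_iter = 100) {
  stopifnot(inherits(h, "haplotype_set"))
  seqs <- h$seqs
  if (nrow(seqs) < 2) stop("need at least two haplotypes")
  observed <- rownames(seqs)
  n_median <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- hamming_matrix(seqs)
    ed <- msn_edges(d, epsilon = epsilon)
    adj <- matrix(FALSE, nrow(seqs), nrow(seqs),
                  dimnames = dimnames(d))
    adj[cbind(ed$from, ed$to)] <- TRUE
    adj <- adj | t(adj)
    # candidate triplets: u-v and u-w linked (v, w need not be)
    cand <- list()
    labs <- rownames(seqs)
    for (u in seq_along(labs)) {
      nb <- which(adj[u, ])
      if (length(nb) < 2) next
      prs <- utils::combn(nb, 2)
      for (cidx in seq_len(ncol(prs))) {
        v <- prs[1, cidx]; w <- prs[2, cidx]
        med <- median_vector(seqs[u, ], seqs[v, ], seqs[w, ])
        if (is.null(med)) next
        key <- paste(med, collapse = "")
        if (key %in% apply(seqs, 1, paste, collapse = "")) next
        cost_new <- sum(med != seqs[u, ]) + sum(med != seqs[v, ]) +
          sum(med != seqs[w, ])
        # a useful median is a Steiner point: strictly cheaper than the
        # current local connection through u
        if (cost_new < d[u, v] + d[u, w])
          cand[[length(cand) + 1]] <- list(seq = med, cost = cost_new,
                                           key = key)
      }
    }
    if (!length(cand)) { converged <- TRUE; break }
    costs <- vapply(cand, `[[`, numeric(1), "cost")
    keys <- vapply(cand, `[[`, character(1), "key")
    best <- which(costs == min(costs))
    best <- best[order(keys[best])][1]   # deterministic tie-break
    n_median <- n_median + 1
    seqs <- rbind(seqs, cand[[best]]$seq)
    rownames(seqs)[nrow(seqs)] <- paste0("mv", n_median)
  }
  if (!converged)
    stop("median-joining did not reach a fixpoint within ", max_iter,
         " rounds (", nrow(seqs), " nodes, ", n_median, " medians added)")
  # prune median vectors that lie redundantly on a path
  repeat {
    d <- hamming_matrix(seqs)
    ed <- msn_edges(d, epsilon = epsilon)
    medians <- setdiff(rownames(seqs), observed)
    drop <- NULL
    for (m in medians) {
      deg <- sum(ed$from == m | ed$to == m)
      if (deg <= 1) { drop <- m; break }
      if (deg == 2) {
        inc <- ed[ed$from == m | ed$to == m, ]
        other <- setdiff(c(inc$from, inc$to), m)
        if (d[other[1], other[2]] == sum(inc$steps)) { drop <- m; break }
      }
    }
    if (is.null(drop)) break
    seqs <- seqs[rownames(seqs) != drop, , drop = FALSE]
  }
  d <- hamming_matrix(seqs)
  ed <- msn_edges(d, epsilon = epsilon)
  nodes <- data.frame(
    label = rownames(seqs),
    freq = ifelse(rownames(seqs) %in% observed,
                  h$freq[rownames(seqs)], 0),
    median = !(rownames(seqs) %in% observed),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = ed, seqs = seqs),
            class = "mj_network")
}

# per-site majority among three sequences; NULL when any site has a
# three-way tie (no new ambiguity is introduced)
median_vector <- function(a, b, c) {
  out <- character(length(a))
  for (i in seq_along(a)) {
    v <- c(a[i], b[i], c[i])
    tab <- table(v)
    if (max(tab) == 1) return(NULL)
    out[i] <- names(tab)[which.max(tab)]
  }
  out
}

#' @export
print.mj_network <- function(x, ...) {
  cat("Median-joining network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$median), "median vectors ),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write a haplotype network as edge-list and frequency TSVs
#'
#' @param net an `mj_network`.
#' @param edges_path,freq_path output TSV paths (`NULL` to skip either).
#' @export
write_network <- function(net, edges_path, freq_path = NULL) {
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(freq_path))
    utils::write.table(net$nodes, freq_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(edges_path)
}
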