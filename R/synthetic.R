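#' Six-deme colonization demography (point-estimate backbone)
#'
#' The backbone model used throughout: six lake/sea demes -- a Norwegian
#' (NOR), Baltic (BAL), Alpine (ALP), Scottish (LOM), Welsh (LTE) and
#' English (RTA) population -- joined backward in time by four splits
#' (English from Welsh at 3,887 generations, Welsh lineage from Alpine at
#' 5,965, Scottish from the Alpine trunk at 18,674, Baltic at 23,205 and
#' Norwegian at 26,247), with pulse admixture into the Baltic deme (0.46
#' from the Norwegian lineage at 6,663 generations, 0.15 from the Scottish
#' at 4,433) and a 0.15 pulse from the Scottish into the Welsh deme at
#' 3,473 generations.  Split times and admixture proportions are inferred
#' point estimates; effective sizes are not identifiable from published
#' summaries and are package defaults calibrated so that the model
#' reproduces the observed scale of diversity and differentiation (see the
#' methods vignette).
#'
#' @param sizes named diploid effective sizes for the six demes.
#' @param ancestral_size trunk size older than the oldest split.
#' @param mutation_rate,generation_time,locus_length passed to
#'   [demographic_model()].
#' @return a validated `demographic_model`.
#' @export
six_pop_model <- function(sizes = c(NOR = 12000, BAL = 25000, ALP = 12000,
                                    LOM = 6000, LTE = 12000, RTA = 10000),
                          ancestral_size = 25000,
                          mutation_rate = 1e-8, generation_time = 3.5,
                          locus_length = 142) {
  demographic_model(
    sizes = sizes,
    events = list(
      pulse_event("LOM", "LTE", 0.15, 3473),
      split_event("RTA", "LTE", 3887),
      pulse_event("LOM", "BAL", 0.15, 4433),
      split_event("LTE", "ALP", 5965),
      pulse_event("NOR", "BAL", 0.46, 6663),
      split_event("LOM", "ALP", 18674),
      split_event("BAL", "ALP", 23205),
      split_event("NOR", "ALP", 26247),
      size_event("ALP", ancestral_size, 26247)
    ),
    mutation_rate = mutation_rate,
    generation_time = generation_time,
    locus_length = locus_length)
}

#' Study template: an eleven-population ddRAD survey design
#'
#' Extends the six-deme backbone with five satellite demes that mirror the
#' within-region structure of a multi-lake survey: a second Scottish loch
#' (ECK) off LOM, three further English lakes (HAW, UWA, BWA) off RTA, and
#' a Siberian-lineage river population (RUS) off NOR.  Satellite attachment
#' times and all effective sizes are synthetic defaults calibrated against
#' the observed within-region differentiation scale; sample sizes per
#' population (3-11 diploids) mirror the study design.  The template fully
#' specifies the generator: demography, samples, locus count and length,
#' pseudo-chromosome layout, per-genotype read-depth distribution (negative
#' binomial) and per-population missingness.
#'
#' @param n_loci number of ddRAD loci.
#' @param locus_length locus length in bp.
#' @param n_chrom,chrom_length pseudo-chromosome count and length (bp).
#' @param depth_mean,depth_size negative-binomial read-depth parameters.
#' @param missingness named per-population missing-call probabilities.
#' @param samples named diploid sample sizes.
#' @return a `study_template` list with elements `model`, `samples`,
#'   `n_loci`, `locus_length`, `n_chrom`, `chrom_length`, `depth_mean`,
#'   `depth_size`, `missingness`.
#' @export
study_template <- function(n_loci = 20000, locus_length = 142,
                           n_chrom = 40, chrom_length = 5e7,
                           depth_mean = 18, depth_size = 30,
                           missingness = NULL,
                           samples = c(NOR = 10, BAL = 8, RUS = 4,
                                       ECK = 10, LOM = 10, ALP = 9,
                                       LTE = 7, HAW = 3, RTA = 10,
                                       BWA = 11, UWA = 9)) {
  base <- six_pop_model(locus_length = locus_length)
  model <- attach_deme(base, "ECK", 4000, "LOM", 3500)
  model <- attach_deme(model, "RUS", 6000, "NOR", 12000)
  model <- attach_deme(model, "UWA", 8000, "RTA", 2500)
  model <- attach_deme(model, "BWA", 8000, "UWA", 800)
  model <- attach_deme(model, "HAW", 6000, "RTA", 1200)
  if (is.null(missingness))
    missingness <- c(NOR = 0.04, BAL = 0.05, RUS = 0.15, ECK = 0.03,
                     LOM = 0.03, ALP = 0.05, LTE = 0.04, HAW = 0.06,
                     RTA = 0.03, BWA = 0.04, UWA = 0.04)
  stopifnot(all(names(samples) %in% model$demes),
            all(names(samples) %in% names(missingness)),
            all(missingness >= 0 & missingness <= 1))
  structure(list(model = model, samples = samples, n_loci = n_loci,
                 locus_length = locus_length, n_chrom = n_chrom,
                 chrom_length = chrom_length, depth_mean = depth_mean,
                 depth_size = depth_size,
                 missingness = missingness[names(samples)]),
            class = "study_template")
}

#' Generate a synthetic ddRAD SNP dataset (VCF + popmap + truth record)
#'
#' Draws genotypes locus-by-locus from the template demography, scatters
#' the loci over pseudo-chromosomes (each locus a contiguous short
#' fragment; SNPs get distinct offsets within it), overlays negative
#' binomial per-genotype read depths and per-population missingness, and
#' writes a VCF 4.2, a two-column population map and a JSON truth record
#' holding every generating parameter.
#'
#' @param template a [study_template()].
#' @param dir output directory (created if needed); `NULL` returns the
#'   genotype matrix without writing files.
#' @param seed integer seed (byte-identical output for equal seeds).
#' @return list with `genotypes` (a [genotype_matrix]), `truth`, and file
#'   paths (`vcf`, `popmap`, `truth_json`) when `dir` is given.
#' @export
generate_vcf <- function(template, dir = NULL, seed = 1) {
  stopifnot(inherits(template, "study_template"))
  g <- simulate_genotypes(template$model, template$samples,
                          n_loci = template$n_loci, seed = seed)
  set.seed(seed + 1)
  # place loci: chromosome and start position per locus, offsets within
  loci <- sort(unique(g$sites$locus))
  n_per_chr <- ceiling(length(loci) / template$n_chrom)
  chr_of <- rep(seq_len(template$n_chrom), each = n_per_chr)[seq_along(loci)]
  start_of <- integer(length(loci))
  slot_w <- template$locus_length + 10   # non-overlapping locus slots
  n_slots <- floor(template$chrom_length / slot_w)
  for (ch in unique(chr_of)) {
    k <- sum(chr_of == ch)
    slots <- sort(sample.int(n_slots, k))
    start_of[chr_of == ch] <- (slots - 1L) * slot_w + 1L
  }
  li <- match(g$sites$locus, loci)
  within <- stats::ave(seq_along(li), li, FUN = seq_along)
  offs <- stats::ave(seq_along(li), li, FUN = function(ix)
    sort(sample.int(template$locus_length, length(ix))))
  sites <- data.frame(
    chrom = sprintf("chr%02d", chr_of[li]),
    pos = as.integer(start_of[li] + offs),
    locus = paste0("L", li),
    ref = sample(c("A", "C", "G", "T"), length(li), replace = TRUE),
    alt = NA_character_, stringsAsFactors = FALSE)
  sites$alt <- vapply(sites$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  depth <- if (is.infinite(template$depth_size))
    matrix(template$depth_mean, nrow(g$geno), ncol(g$geno))
  else
    matrix(stats::rnbinom(length(g$geno), mu = template$depth_mean,
                          size = template$depth_size),
           nrow = nrow(g$geno))
  geno <- g$geno
  # RAD dropout is locus-level (a sample misses the whole fragment) and
  # heterogeneous across samples: per-sample rates are the population mean
  # scaled by an exponential weight, so a few bad samples carry most of
  # the missingness
  miss_rate <- pmin(template$missingness[g$pops] *
                      stats::rexp(nrow(geno)), 0.9)
  drop <- matrix(stats::runif(nrow(geno) * length(loci)) < miss_rate,
                 nrow = nrow(geno))
  miss <- drop[, li, drop = FALSE]
  geno[miss] <- NA_integer_
  depth[miss] <- NA
  out_g <- genotype_matrix(geno, g$sample_ids, g$pops, sites, depth = depth)
  truth <- list(seed = seed,
                n_loci = template$n_loci,
                locus_length = template$locus_length,
                mutation_rate = template$model$mutation_rate,
                generation_time = template$model$generation_time,
                sizes = as.list(template$model$sizes),
                samples = as.list(template$samples),
                missingness = as.list(template$missingness),
                depth = list(mean = template$depth_mean,
                             size = template$depth_size),
                events = template$model$events,
                n_snps = ncol(out_g$geno))
  if (is.null(dir))
    return(list(genotypes = out_g, truth = truth))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "data.vcf")
  popmap <- file.path(dir, "popmap.txt")
  tj <- file.path(dir, "truth.json")
  write_vcf(out_g, vcf, popmap_path = popmap)
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(genotypes = out_g, truth = truth, vcf = vcf, popmap = popmap,
       truth_json = tj)
}

#' Planted mitochondrial haplotype genealogy template
#'
#' A small rooted haplotype tree with a planted number of mutations per
#' branch and per-population sampling counts, emulating a two-clade
#' (northern/southern) mtDNA gene: the true pairwise mutation distances,
#' and hence the true network, are known exactly.
#'
#' @param branches data.frame with columns `hap`, `parent` (`NA` for the
#'   root haplotype) and `mutations` (planted steps on the branch).
#' @param counts data.frame with columns `hap`, `pop`, `n` (sampled
#'   sequences per haplotype per population).
#' @export
mtdna_template <- function(branches = NULL, counts = NULL) {
  if (is.null(branches))
    branches <- data.frame(
      hap = c("N1", "N2", "N3", "S1", "S2"),
      parent = c(NA, "N1", "N1", "N1", "S1"),
      mutations = c(0, 1, 2, 8, 1),
      stringsAsFactors = FALSE)
  if (is.null(counts))
    counts <- data.frame(
      hap = c("N1", "N1", "N2", "N3", "S1", "S2"),
      pop = c("NOR", "ALP", "BAL", "LOM", "LTE", "LTE"),
      n = c(10, 6, 5, 17, 3, 2),
      stringsAsFactors = FALSE)
  stopifnot(sum(is.na(branches$parent)) == 1,
            all(stats::na.omit(branches$parent) %in% branches$hap),
            all(counts$hap %in% branches$hap), all(counts$n >= 0))
  structure(list(branches = branches, counts = counts),
            class = "mtdna_template")
}

#' Generate an aligned mtDNA FASTA with a known haplotype network
#'
#' Draws a random root sequence of the requested length, walks the planted
#' genealogy placing each branch's mutations at distinct, previously
#' unmutated positions (so planted step counts equal Hamming distances),
#' and emits the sampled sequences named `<pop>_<i>`.
#'
#' @param template an [mtdna_template()].
#' @param length sequence length in bp.
#' @param seed integer seed.
#' @param path optional FASTA output path.
#' @return list with `aln` (character matrix), `haplotypes` (true sequence
#'   per haplotype) and `template`.
#' @export
generate_mtdna <- function(template = mtdna_template(), length = 975,
                           seed = 1, path = NULL) {
  stopifnot(inherits(template, "mtdna_template"))
  set.seed(seed)
  br <- template$branches
  root <- br$hap[is.na(br$parent)]
  base <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  total_mut <- sum(br$mutations)
  if (total_mut > length) stop("more planted mutations than sites")
  mut_pos <- sample.int(length, total_mut)
  haps <- list()
  haps[[root]] <- base
  used <- 0
  pending <- setdiff(br$hap, root)
  while (length(pending)) {
    ready <- pending[br$parent[match(pending, br$hap)] %in% names(haps)]
    if (!length(ready)) stop("cyclic haplotype template")
    for (hp in ready) {
      row <- match(hp, br$hap)
      s <- haps[[br$parent[row]]]
      nm <- br$mutations[row]
      if (nm > 0) {
        pos <- mut_pos[used + seq_len(nm)]
        used <- used + nm
        for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
      }
      haps[[hp]] <- s
    }
    pending <- setdiff(pending, ready)
  }
  cnt <- template$counts[template$counts$n > 0, , drop = FALSE]
  seq_names <- character(0)
  rows <- list()
  idx_by_pop <- list()
  for (r in seq_len(nrow(cnt))) {
    p <- cnt$pop[r]
    for (i in seq_len(cnt$n[r])) {
      idx_by_pop[[p]] <- (idx_by_pop[[p]] %||% 0) + 1
      seq_names <- c(seq_names, paste0(p, "_", idx_by_pop[[p]]))
      rows[[length(rows) + 1]] <- haps[[cnt$hap[r]]]
    }
  }
  aln <- do.call(rbind, rows)
  rownames(aln) <- seq_names
  if (!is.null(path)) {
    con <- file(path, "w")
    for (i in seq_len(nrow(aln)))
      writeLines(c(paste0(">", seq_names[i]),
                   paste(aln[i, ], collapse = "")), con)
    close(con)
  }
  list(aln = aln, haplotypes = haps, template = template)
}
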