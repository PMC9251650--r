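test_that("model validation catches impossible histories", {
  expect_silent(demographic_model(c(A = 1000, B = 500),
                                  events = list(split_event("B", "A", 100))))
  # several demes with no joining splits
  expect_error(demographic_model(c(A = 1, B = 1) * 1000), "split")
  # pulse proportion out of range
  expect_error(demographic_model(
    c(A = 1000, B = 1000),
    events = list(pulse_event("A", "B", 1.2, 50),
                  split_event("B", "A", 100))), "\\[0, 1\\]")
  # split from a nonexistent deme
  expect_error(demographic_model(
    c(A = 1000, B = 1000),
    events = list(split_event("C", "A", 100),
                  split_event("B", "A", 200))), "unknown")
  # pulse at a time later than the donor deme's split
  expect_error(demographic_model(
    c(A = 1000, B = 1000, C = 1000),
    events = list(split_event("C", "A", 50),
                  pulse_event("C", "B", 0.1, 80),
                  split_event("B", "A", 100))), "not extant")
  # the six-deme point-estimate model is valid
  expect_s3_class(six_pop_model(), "demographic_model")
})

test_that("single-deme expectations match coalescent theory", {
  m <- demographic_model(c(A = 1000))
  s2 <- simulate_sites(m, genes = c(A = 2), n_loci = 10000, seed = 1,
                       mu_len = 0)
  se <- stats::sd(s2$tmrca) / sqrt(length(s2$tmrca))
  expect_lt(abs(mean(s2$tmrca) - 2000), 3 * se)
  s8 <- simulate_sites(m, genes = c(A = 8), n_loci = 10000, seed = 2,
                       mu_len = 0)
  expected_len <- 4 * 1000 * sum(1 / (1:7))
  se8 <- stats::sd(s8$tlen) / sqrt(length(s8$tlen))
  expect_lt(abs(mean(s8$tlen) - expected_len), 3 * se8)
  # E[segregating sites] = mu_len * E[total length]
  sm <- simulate_sites(m, genes = c(A = 8), n_loci = 5000, seed = 3,
                       mu_len = 1e-3)
  expect_lt(abs(nrow(sm$counts) / 5000 - 1e-3 * expected_len),
            3 * sqrt(nrow(sm$counts)) / 5000)
})

test_that("cross-deme coalescence never predates the split", {
  m <- demographic_model(c(A = 500, B = 500),
                         events = list(split_event("B", "A", 800)))
  for (s in 1:25) {
    tr <- simulate_genealogy(m, samples = c(A = 2, B = 2), seed = s)
    depth <- ape::node.depth.edgelength(tr)
    tmrca <- max(depth)
    times <- tmrca - depth            # node ages
    a_tips <- grep("^A_", tr$tip.label)
    b_tips <- grep("^B_", tr$tip.label)
    anc <- ape::getMRCA(tr, c(a_tips[1], b_tips[1]))
    expect_gt(times[anc], 800)
  }
})

test_that("mutations on a fixed genealogy follow branch descent", {
  m <- demographic_model(c(A = 800))
  tr <- simulate_genealogy(m, samples = c(A = 4), seed = 4)
  loc <- simulate_locus(tr, mu = 1e-5, L = 100, seed = 9)
  if (nrow(loc$carriers) > 0) {
    expect_true(all(loc$counts >= 1 & loc$counts <= 8))
    expect_equal(loc$counts, rowSums(loc$carriers))
  }
  # zero-length tree yields zero sites
  tr0 <- tr; tr0$edge.length[] <- 0
  expect_equal(nrow(simulate_locus(tr0, 1e-3, 100, 1)$carriers), 0L)
})

test_that("folded single-deme SFS matches the closed-form shape", {
  # low mutation rate keeps almost every locus single-site, so the sites
  # entering the chi-square are effectively independent draws from the
  # marginal frequency law
  m <- demographic_model(c(A = 1000))
  ss <- simulate_sites(m, genes = c(A = 8), n_loci = 1000000, seed = 5,
                       mu_len = 1e-5)
  d <- ss$counts[, 1]
  counts <- tabulate(pmin(d, 8L - d), nbins = 4)
  expect_gt(sum(counts), 1e5)
  i <- 1:4
  p <- (1 / i + 1 / (8 - i)) / (1 + (i == 4))
  gof <- stats::chisq.test(counts, p = p / sum(p))
  expect_gt(gof$p.value, 1e-3)
})

test_that("MSFS accounting, folding and reproducibility invariants hold", {
  m <- demographic_model(c(A = 2000, B = 1000),
                         events = list(split_event("B", "A", 1500)))
  sf <- simulate_msfs(m, samples = c(A = 3, B = 2), n_loci = 3000, seed = 6)
  expect_equal(sum(sf$counts) + sf$monomorphic, 3000 * m$locus_length)
  n <- sum(sf$sample_sizes)
  expect_true(all(rowSums(sf$idx) <= n / 2))
  # at exactly half frequency the lexicographically smaller index is kept
  half <- sf$idx[rowSums(sf$idx) == n / 2, , drop = FALSE]
  if (nrow(half)) {
    comp <- sweep(-half, 2, sf$sample_sizes, `+`)
    for (r in seq_len(nrow(half))) {
      d <- which(half[r, ] != comp[r, ])
      if (length(d)) expect_lt(half[r, d[1]], comp[r, d[1]])
    }
  }
  # bit-for-bit reproducibility and per-locus substreams
  expect_identical(simulate_msfs(m, samples = c(A = 3, B = 2),
                                 n_loci = 300, seed = 7),
                   simulate_msfs(m, samples = c(A = 3, B = 2),
                                 n_loci = 300, seed = 7))
  s1 <- simulate_sites(m, samples = c(A = 3, B = 2), n_loci = 200, seed = 8)
  s2 <- simulate_sites(m, samples = c(A = 3, B = 2), n_loci = 350, seed = 8)
  expect_identical(s1$tmrca, s2$tmrca[1:200])
})

test_that("pulse admixture moves F_ST monotonically toward panmixia", {
  fst_at <- function(alpha) {
    ev <- list(split_event("B", "A", 4000))
    if (alpha > 0) ev <- c(list(pulse_event("A", "B", alpha, 10)), ev)
    m <- demographic_model(c(A = 1000, B = 1000), events = ev)
    g <- simulate_genotypes(m, samples = c(A = 6, B = 6), n_loci = 3000,
                            seed = 11)
    wc_fst(g, "A", "B")$theta
  }
  f <- vapply(c(0, 0.5, 1), fst_at, numeric(1))
  expect_gt(f[1], f[2] + 0.02)
  expect_gt(f[2], f[3] + 0.02)
  expect_lt(f[3], 0.05)               # full replacement is near-panmictic
})

test_that("two-deme spectra agree with an independent coalescent simulator", {
  skip_if_not(nzchar(Sys.which("python")), "python not on PATH")
  # msprime as the cross-simulator oracle on an identical split model
  script <- '
import msprime, json
dem = msprime.Demography()
dem.add_population(name="A", initial_size=1000)
dem.add_population(name="B", initial_size=1000)
dem.add_population(name="anc", initial_size=1000)
dem.add_population_split(time=1000, derived=["A", "B"], ancestral="anc")
S = []
div = []
for rep in range(300):
    ts = msprime.sim_ancestry(samples={"A": 3, "B": 3}, demography=dem,
                              sequence_length=100, random_seed=rep + 1)
    mts = msprime.sim_mutations(ts, rate=1e-5, random_seed=rep + 1)
    S.append(mts.num_sites)
    div.append(float(mts.divergence(sample_sets=[range(0, 6), range(6, 12)],
                                    mode="site")))
print(json.dumps({"mean_S": sum(S) / len(S),
                  "mean_div": sum(div) / len(div)}))
'
  f <- tempfile(fileext = ".py"); writeLines(script, f)
  out <- suppressWarnings(system2("python", f, stdout = TRUE, stderr = FALSE))
  skip_if(length(out) == 0, "msprime unavailable")
  ref <- jsonlite::fromJSON(out[length(out)])
  m <- demographic_model(c(A = 1000, B = 1000),
                         events = list(split_event("B", "A", 1000)),
                         mutation_rate = 1e-5, locus_length = 100)
  sim <- simulate_sites(m, samples = c(A = 3, B = 3), n_loci = 1000,
                        seed = 21)
  mean_S <- nrow(sim$counts) / 1000
  # mean pairwise divergence between demes per bp
  pa <- sim$counts[, "A"] / 6; pb <- sim$counts[, "B"] / 6
  mean_div <- sum(pa * (1 - pb) + pb * (1 - pa)) / (1000 * 100)
  expect_lt(abs(mean_S - ref$mean_S) / ref$mean_S, 0.15)
  expect_lt(abs(mean_div - ref$mean_div) / ref$mean_div, 0.15)
})
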