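test_that("msfs_from_genotypes folds per-deme minor-allele counts", {
  # 1 deme, 2 diploids, one het: entry (1)
  g <- toy_genotypes(matrix(c(0L, 1L), 2, 1), rep("A", 2))
  m <- msfs_from_genotypes(g, "A")
  expect_equal(unname(m$idx[1, ]), 1L)
  expect_equal(m$counts, 1)
  # 2 demes, fixed different: tie folds to the lexicographically smaller
  g2 <- toy_genotypes(matrix(c(2L, 2L, 0L, 0L), 4, 1),
                      rep(c("A", "B"), each = 2))
  m2 <- msfs_from_genotypes(g2, c("A", "B"))
  expect_equal(unname(m2$idx[1, ]), c(0L, 4L))
  # total equals SNP count on synthetic data
  tpl <- study_template(n_loci = 120, samples = c(NOR = 3, LOM = 3),
                        missingness = c(NOR = 0, LOM = 0))
  gg <- generate_vcf(tpl, seed = 5)$genotypes
  mm <- msfs_from_genotypes(gg, c("NOR", "LOM"))
  expect_equal(sum(mm$counts), ncol(gg$geno))
  # missing genotypes are refused with the site named
  g3 <- toy_genotypes(matrix(c(0L, NA, 1L, 1L), 2, 2), rep("A", 2))
  expect_error(msfs_from_genotypes(g3, "A"), "site")
})

test_that("hypergeometric projection matches hand weights and conserves mass", {
  sizes <- c(A = 4L)
  m <- msfs(matrix(2L, 1, 1), 10, sizes)
  m <- correct_monomorphic(m, 100)
  p <- project_msfs(m, 2)
  # d = 2 of n = 4 projects to k = 2 as (1/6, 4/6, 1/6); the 0 and 2 cells
  # are monomorphic in the subsample and join the monomorphic entry
  expect_equal(p$counts[p$idx[, 1] == 1], 10 * 4 / 6)
  expect_equal(p$monomorphic, 90 + 2 * 10 / 6)
  expect_equal(sum(p$counts) + p$monomorphic, 100)
  # identity when k = n
  expect_equal(project_msfs(m, 4)$counts, m$counts)
  # enumeration oracle on random 1-D entries
  set.seed(41)
  for (i in 1:10) {
    n <- sample(4:8, 1); k <- sample(2:(n - 1), 1); d <- sample(1:n, 1)
    mo <- msfs(matrix(as.integer(d), 1, 1), 1, c(A = n), monomorphic = 0)
    pr <- project_msfs(mo, k)
    oracle <- project_enumeration_oracle(d, n, k)
    # fold the oracle distribution
    fold <- rep(0, k + 1)
    for (j in 0:k) {
      jj <- min(j, k - j)
      fold[jj + 1] <- fold[jj + 1] + oracle[j + 1]
    }
    got <- rep(0, k + 1)
    got[pr$idx[, 1] + 1] <- pr$counts
    got[1] <- got[1] + pr$monomorphic
    expect_equal(got[1] + sum(got[-1]), 1, tolerance = 1e-9)
    expect_equal(got[-1], fold[2:(k + 1)], tolerance = 1e-9)
  }
})

test_that("projection composes: k1 then k2 equals k2 directly", {
  m <- demographic_model(c(A = 2000, B = 1000),
                         events = list(split_event("B", "A", 1500)))
  sf <- simulate_msfs(m, samples = c(A = 6, B = 6), n_loci = 2000, seed = 9)
  p_direct <- project_msfs(sf, 6)
  p_two <- project_msfs(project_msfs(sf, 9), 6)
  key_d <- paste(p_direct$idx[, 1], p_direct$idx[, 2])
  key_t <- paste(p_two$idx[, 1], p_two$idx[, 2])
  expect_setequal(key_d[p_direct$counts > 1e-12],
                  key_t[p_two$counts > 1e-12])
  hit <- match(key_d, key_t)
  expect_equal(p_two$counts[hit], p_direct$counts, tolerance = 1e-9)
  expect_equal(p_two$monomorphic, p_direct$monomorphic, tolerance = 1e-9)
})

test_that("monomorphic correction is exact arithmetic with guards", {
  m <- msfs(matrix(1L, 1, 1), 100, c(A = 4L))
  expect_equal(correct_monomorphic(m, 1000)$monomorphic, 900)
  expect_equal(correct_monomorphic(m, 100)$monomorphic, 0)
  expect_error(correct_monomorphic(m, 50), "smaller")
})

test_that("total_sites scales the inferred effective size inversely", {
  # 1-deme theta fit: doubling the invariant span halves the implied N
  m <- demographic_model(c(A = 5000))
  obs <- simulate_msfs(m, samples = c(A = 4), n_loci = 4000, seed = 10)
  fit_n <- function(total_sites) {
    o <- correct_monomorphic(obs, total_sites)
    pr <- profile_composite_likelihood(
      o, m, free_param("N", "size", "A", 500, 60000),
      grid = exp(seq(log(800), log(40000), length.out = 25)),
      n_sims = 4000, seeds = 1)
    attr(pr, "estimate")
  }
  n1 <- fit_n(4000 * 142)
  n2 <- fit_n(2 * 4000 * 142)
  expect_equal(n2 / n1, 0.5, tolerance = 0.25)
  expect_equal(n1, 5000, tolerance = 0.35)
})

test_that("flat-text round trip and dadi-style import work", {
  m <- demographic_model(c(A = 1000, B = 500),
                         events = list(split_event("B", "A", 700)))
  sf <- simulate_msfs(m, samples = c(A = 3, B = 2), n_loci = 500, seed = 12)
  f <- tempfile(fileext = ".msfs")
  write_msfs(sf, f)
  back <- read_msfs(f)
  expect_equal(back$idx, sf$idx)
  expect_equal(back$counts, sf$counts)
  expect_equal(back$sample_sizes, sf$sample_sizes)
  expect_equal(back$monomorphic, sf$monomorphic)
  # dadi-style 1-D flat spectrum: n = 4 genes, cells 0..4
  f2 <- tempfile()
  writeLines(c("5", "900 30 20 10 5"), f2)
  d <- read_msfs(f2)
  expect_equal(d$monomorphic, 905)               # fixed cells pooled
  got <- stats::setNames(rep(0, 2), 1:2)
  agg <- tapply(d$counts, d$idx[, 1], sum)
  got[names(agg)] <- agg
  expect_equal(unname(got), c(30 + 10, 20))      # folded
})

test_that("downsampling yields fully genotyped matrices", {
  set.seed(43)
  g <- random_genotypes(c(A = 5, B = 4), n_sites = 12, miss = 0)
  # identity when k equals deme size and nothing is missing
  gd <- downsample_genotypes(g, 4, seed = 1)
  expect_equal(ncol(gd$geno), 12L)
  # the sample carrying all missingness is excluded
  g$geno[2, ] <- NA                                # sample 2 in pop A
  g2 <- downsample_genotypes(g, 4, seed = 1)
  expect_false(g$sample_ids[2] %in% g2$sample_ids)
  expect_false(anyNA(g2$geno))
  expect_s3_class(msfs_from_genotypes(g2, c("A", "B")), "msfs")
  expect_error(downsample_genotypes(g, 6, seed = 1), "fewer")
})

test_that("composite likelihood follows the written formula and is linear", {
  m <- demographic_model(c(A = 1500))
  obs <- simulate_msfs(m, samples = c(A = 4), n_loci = 800, seed = 14)
  obs <- correct_monomorphic(obs, 800 * m$locus_length)
  # independent transcription of the estimator from its definition
  sim <- simulate_msfs(m, genes = obs$sample_sizes, n_loci = 2000, seed = 77)
  total <- 2000 * m$locus_length
  p <- rep(0, nrow(obs$idx))
  for (i in seq_len(nrow(obs$idx))) {
    hit <- which(sim$idx[, 1] == obs$idx[i, 1])
    if (length(hit)) p[i] <- sim$counts[hit] / total
  }
  pmin_ <- 1 / (10 * total)
  by_hand <- sum(obs$counts * log(pmax(p, pmin_))) +
    obs$monomorphic * log(sim$monomorphic / total)
  expect_equal(composite_log_likelihood(obs, m, n_sims = 2000, seed = 77),
               by_hand, tolerance = 1e-8)
  # doubling every observed count doubles the likelihood
  obs2 <- obs; obs2$counts <- 2 * obs2$counts; obs2$monomorphic <- 2 * obs2$monomorphic
  expect_equal(composite_log_likelihood(obs2, m, n_sims = 2000, seed = 77),
               2 * by_hand, tolerance = 1e-8)
  # invariant to adding zero-count entries
  obs3 <- obs
  obs3$idx <- rbind(obs3$idx, matrix(2L, 1, 1))
  obs3$counts <- c(obs3$counts, 0)
  expect_equal(composite_log_likelihood(obs3, m, n_sims = 2000, seed = 77),
               by_hand, tolerance = 1e-8)
})

test_that("no alternative parameter beats the truth on a likelihood grid", {
  m <- demographic_model(c(A = 3000))
  obs <- simulate_msfs(m, samples = c(A = 4), n_loci = 6000, seed = 15)
  grid <- c(1000, 1800, 3000, 5000, 9000)
  pr <- profile_composite_likelihood(obs, m,
                                     free_param("N", "size", "A", 500, 20000),
                                     grid = grid, n_sims = 6000, seeds = 1:2,
                                     smooth_pts = 0)
  expect_equal(pr$value[which.max(pr$cl)], 3000)
})
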