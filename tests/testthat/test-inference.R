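test_that("single-deme size is recovered by the optimizer", {
  m <- demographic_model(c(A = 10000))
  obs <- simulate_msfs(m, samples = c(A = 4), n_loci = 10000, seed = 16)
  fit <- fit_model(m, list(free_param("N", "size", "A", 100, 1e6)),
                   obs, n_starts = 4, n_cycles = 3, n_sims = 4000, seed = 2)
  expect_gt(fit$par["N"], 5000)
  expect_lt(fit$par["N"], 20000)
  expect_true(all(fit$cl >= fit$per_start$cl))
  # reproducible under the same seed
  fit2 <- fit_model(m, list(free_param("N", "size", "A", 100, 1e6)),
                    obs, n_starts = 4, n_cycles = 3, n_sims = 4000, seed = 2)
  expect_identical(fit$par, fit2$par)
})

test_that("a fully fixed model reduces to one likelihood evaluation", {
  m <- demographic_model(c(A = 2000))
  obs <- simulate_msfs(m, samples = c(A = 3), n_loci = 500, seed = 17)
  fit <- fit_model(m, list(), obs, n_sims = 1000, seed = 3)
  expect_length(fit$par, 0)
  expect_equal(fit$cl, composite_log_likelihood(obs, m, 1000, seed = 3))
})

test_that("two-deme split time is recovered within a grid step", {
  truth <- 2000
  m <- demographic_model(c(A = 2000, B = 2000),
                         events = list(split_event("B", "A", truth)))
  obs <- simulate_msfs(m, samples = c(A = 5, B = 5), n_loci = 8000, seed = 18)
  grid <- seq(500, 5000, by = 375)
  pr <- profile_composite_likelihood(
    obs, m, free_param("T", "split_time", "B", 100, 8000),
    grid = grid, n_sims = 8000, seeds = 1:2)
  expect_lt(abs(attr(pr, "estimate") - truth), 2 * 375 + 1)
})

test_that("model comparison ranks the generating topology first", {
  # ((A,B),C) truth against the misspecified ((A,C),B)
  make <- function(first, second, t1, t2) {
    demographic_model(c(A = 2000, B = 2000, C = 2000),
                      events = list(split_event(first, "A", t1),
                                    split_event(second, "A", t2)))
  }
  wins <- 0
  for (r in 1:4) {
    truth <- make("B", "C", 600, 4000)
    obs <- simulate_msfs(truth, samples = c(A = 4, B = 4, C = 4),
                         n_loci = 3000, seed = 100 + r)
    fits <- list(
      true_topo = fit_model(make("B", "C", 600, 4000),
                            list(free_param("T1", "split_time", "B", 100, 3000),
                                 free_param("T2", "split_time", "C", 3000, 9000)),
                            obs, n_starts = 2, n_cycles = 2, n_sims = 2000,
                            seed = r),
      wrong_topo = fit_model(make("C", "B", 600, 4000),
                             list(free_param("T1", "split_time", "C", 100, 3000),
                                  free_param("T2", "split_time", "B", 3000, 9000)),
                             obs, n_starts = 2, n_cycles = 2, n_sims = 2000,
                             seed = r))
    tab <- compare_models(fits)
    if (tab$model[1] == "true_topo") wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("identical models tie in input order; AIC punishes free parameters", {
  m <- demographic_model(c(A = 2000))
  obs <- simulate_msfs(m, samples = c(A = 4), n_loci = 2000, seed = 19)
  f0 <- fit_model(m, list(), obs, n_sims = 1500, seed = 5)
  f0b <- fit_model(m, list(), obs, n_sims = 1500, seed = 5)
  tab <- compare_models(list(first = f0, second = f0b))
  expect_equal(tab$model, c("first", "second"))
  # an unnecessary free parameter gains almost no likelihood, so AIC
  # (2k - 2CL) moves against it by ~2k
  f1 <- fit_model(m, list(free_param("N", "size", "A", 500, 8000)),
                  obs, n_starts = 2, n_cycles = 2, n_sims = 1500, seed = 5)
  tab2 <- compare_models(list(fixed = f0, free = f1))
  expect_lt(abs(f1$cl - f0$cl) / abs(f0$cl), 0.01)
  expect_equal(tab2$AIC[tab2$model == "free"] -
                 tab2$AIC[tab2$model == "fixed"],
               2 - 2 * (f1$cl - f0$cl), tolerance = 1e-9)
  # different observed data are refused
  obs2 <- simulate_msfs(m, samples = c(A = 4), n_loci = 1999, seed = 20)
  f2 <- fit_model(m, list(), obs2, n_sims = 1500, seed = 5)
  expect_error(compare_models(list(f0, f2)), "different observed")
})

test_that("hierarchical building recovers the generating attachment", {
  truth <- demographic_model(
    c(A = 2000, B = 2000, C = 2000),
    events = list(split_event("B", "A", 3000), split_event("C", "B", 700)))
  base <- demographic_model(c(A = 2000, B = 2000),
                            events = list(split_event("B", "A", 3000)))
  wins <- 0
  for (r in 1:3) {
    obs <- simulate_msfs(truth, samples = c(A = 4, B = 4, C = 4),
                         n_loci = 2500, seed = 200 + r)
    hb <- hierarchical_build(
      list(obs), base,
      base_free = list(free_param("T_B", "split_time", "B", 500, 8000)),
      levels = list(list(
        deme = "C", size_range = c(500, 8000),
        candidates = list(list(parent = "A", time_range = c(100, 2500)),
                          list(parent = "B", time_range = c(100, 2500))))),
      n_starts = 2, n_cycles = 2, n_sims = 2000, seed = 30 + r)
    if (hb$levels[[1]]$chosen == 2) wins <- wins + 1
    expect_s3_class(validate_model(hb$model), "demographic_model")
  }
  expect_gte(wins, 2)
  # a single candidate degenerates to a sequential fit
  obs <- simulate_msfs(truth, samples = c(A = 4, B = 4, C = 4),
                       n_loci = 1500, seed = 250)
  hb1 <- hierarchical_build(
    list(obs), base,
    base_free = list(free_param("T_B", "split_time", "B", 500, 8000)),
    levels = list(list(deme = "C", size_range = c(500, 8000),
                       candidates = list(list(parent = "B",
                                              time_range = c(100, 2500))))),
    n_starts = 2, n_cycles = 1, n_sims = 1000, seed = 31)
  expect_equal(hb1$levels[[1]]$chosen, 1)
  expect_error(hierarchical_build(
    list(obs), base, list(),
    levels = list(list(deme = "C", size_range = c(500, 8000),
                       candidates = list()))), "candidates")
})

test_that("bootstrap intervals tighten with more data and stay ordered", {
  m <- demographic_model(c(A = 4000))
  free <- list(free_param("N", "size", "A", 500, 50000))
  width_at <- function(n_loci, seed) {
    obs <- simulate_msfs(m, samples = c(A = 4), n_loci = n_loci, seed = seed)
    fit <- fit_model(m, free, obs, n_starts = 2, n_cycles = 2,
                     n_sims = 2000, seed = seed)
    ci <- parametric_bootstrap(fit, obs, n_boot = 8, n_opt = 2,
                               n_cycles = 1, n_sims = 1500, seed = seed)
    expect_true(all(ci$lower <= ci$upper))
    (ci$upper - ci$lower) / ci$point
  }
  expect_lt(width_at(8000, 33), width_at(500, 34) + 0.5)
})
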