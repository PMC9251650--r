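#' Composite log-likelihood of an observed MSFS under a demographic model
#'
#' Entry probabilities are estimated by coalescent simulation of `n_sims`
#' independent loci at the observed sample sizes; the composite
#' log-likelihood is `sum(m_e * log(p_e)) + m_0 * log(p_0)`, treating sites
#' as independent, where `m_0`/`p_0` are the monomorphic count and
#' probability.  Observed entries that were never produced by the
#' simulation are floored at `p_min` (default `1 / (10 * n_sims * L)`), so
#' the likelihood stays finite.
#'
#' When a spectrum has many more cells than a Monte-Carlo estimate can
#' populate, flooring the unpopulated cells biases the likelihood toward
#' parameter values that generate more polymorphism (more observed cells
#' escape the floor).  The estimator here therefore coarsens the
#' multinomial: the `track_cells` most frequent observed cells (ties broken
#' by cell index; stable under rescaling of counts) keep individual
#' probabilities, and all remaining polymorphic cells are pooled into one
#' residual cell whose probability is the total simulated polymorphic mass
#' not assigned to a tracked cell.  With `track_cells = Inf` every observed
#' cell is tracked and the estimator reduces to the plain floored form.
#'
#' @param observed an [msfs] (typically with a corrected monomorphic entry).
#' @param model a [demographic_model()] containing every observed deme.
#' @param n_sims number of simulated loci for the probability estimate.
#' @param seed integer seed; reuse the same seed across parameter values to
#'   compare likelihoods with common random numbers.
#' @param p_min probability floor for tracked cells the simulation never
#'   produced; default `1 / (10 * n_sims * locus_length)`.
#' @param track_cells number of observed cells given individual
#'   probabilities.
#' @return scalar composite log-likelihood.
#' @export
composite_log_likelihood <- function(observed, model, n_sims, seed,
                                     p_min = NULL, track_cells = 1000) {
  stopifnot(inherits(observed, "msfs"))
  model <- validate_model(model)
  missing_demes <- setdiff(names(observed$sample_sizes), model$demes)
  if (length(missing_demes))
    stop("observed demes absent from model: ",
         paste(missing_demes, collapse = ", "))
  sim <- simulate_msfs(model, genes = observed$sample_sizes,
                       n_loci = n_sims, seed = seed)
  total <- n_sims * model$locus_length
  if (is.null(p_min)) p_min <- 1 / (10 * total)
  key_o <- msfs_keys(observed$idx, observed$sample_sizes)
  ord <- order(-observed$counts, key_o)
  track <- utils::head(ord, track_cells)
  rest <- if (length(ord) > length(track)) ord[-seq_along(track)] else
    integer(0)
  key_s <- msfs_keys(sim$idx, sim$sample_sizes)
  hit <- match(key_o[track], key_s)
  p_track <- ifelse(is.na(hit), 0, sim$counts[hit]) / total
  ll <- sum(ifelse(observed$counts[track] > 0,
                   observed$counts[track] * log(pmax(p_track, p_min)), 0))
  m_rest <- sum(observed$counts[rest])
  if (m_rest > 0) {
    p_rest <- sum(sim$counts) / total - sum(p_track)
    ll <- ll + m_rest * log(max(p_rest, p_min))
  }
  if (observed$monomorphic > 0)
    ll <- ll + observed$monomorphic * log(max(sim$monomorphic / total, p_min))
  ll
}

#' Declare a free parameter of a demographic model
#'
#' Free parameters address model components by role, not position, so they
#' survive event re-sorting: split times by the splitting deme, pulse times
#' and proportions by `"donor:recipient"`, sizes by deme name.
#'
#' @param name parameter label.
#' @param type one of `"size"`, `"split_time"`, `"pulse_time"`,
#'   `"pulse_alpha"`.
#' @param target deme name (`size`, `split_time`) or `"donor:recipient"`.
#' @param lower,upper search range.
#' @param log search on log scale (default: everything except proportions).
#' @export
free_param <- function(name, type, target, lower, upper,
                       log = !identical(type, "pulse_alpha")) {
  stopifnot(type %in% c("size", "split_time", "pulse_time", "pulse_alpha"),
            lower < upper, lower >= 0)
  if (log && lower <= 0) stop("log-scale parameter needs lower > 0")
  list(name = name, type = type, target = target,
       lower = lower, upper = upper, log = log)
}

#' @rdname free_param
#' @param m a `demographic_model`.
#' @param spec a `free_param()`.
#' @param value new parameter value.
#' @export
set_model_param <- function(m, spec, value) {
  if (spec$type == "size") {
    if (!spec$target %in% names(m$sizes)) stop("unknown deme: ", spec$target)
    m$sizes[spec$target] <- value
    return(m)
  }
  for (i in seq_along(m$events)) {
    e <- m$events[[i]]
    if (spec$type == "split_time" && e$type == "split" &&
        e$deme == spec$target) {
      m$events[[i]]$time <- value; return(m)
    }
    if (spec$type %in% c("pulse_time", "pulse_alpha") && e$type == "pulse" &&
        paste(e$donor, e$recipient, sep = ":") == spec$target) {
      if (spec$type == "pulse_time") m$events[[i]]$time <- value
      else m$events[[i]]$alpha <- value
      return(m)
    }
  }
  stop("no model component matches free parameter '", spec$name, "'")
}

#' @rdname free_param
#' @export
get_model_param <- function(m, spec) {
  if (spec$type == "size") return(unname(m$sizes[spec$target]))
  for (e in m$events) {
    if (spec$type == "split_time" && e$type == "split" &&
        e$deme == spec$target) return(e$time)
    if (spec$type %in% c("pulse_time", "pulse_alpha") && e$type == "pulse" &&
        paste(e$donor, e$recipient, sep = ":") == spec$target)
      return(if (spec$type == "pulse_time") e$time else e$alpha)
  }
  stop("no model component matches free parameter '", spec$name, "'")
}

apply_params <- function(model, free, par) {
  for (i in seq_along(free)) model <- set_model_param(model, free[[i]], par[i])
  model
}

# Objective closure: composite log-likelihood as a function of the free
# parameter vector; invalid configurations (e.g. a pulse displaced past its
# donor's split) score -Inf.
cl_objective <- function(model, free, observed, n_sims, sim_seed) {
  force(model); force(free)
  function(par) {
    m2 <- tryCatch(validate_model(apply_params(model, free, par)),
                   error = function(e) NULL)
    if (is.null(m2)) return(-Inf)
    composite_log_likelihood(observed, m2, n_sims = n_sims, seed = sim_seed)
  }
}

# Golden-section maximization of f over [lo, hi] (transformed scale),
# fixed number of interior evaluations; returns the best point evaluated.
golden_max <- function(f, lo, hi, iter = 6) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  best_x <- if (f1 >= f2) x1 else x2
  best_f <- max(f1, f2)
  for (i in seq_len(iter)) {
    if (f1 >= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    }
    if (max(f1, f2) > best_f) {
      best_f <- max(f1, f2)
      best_x <- if (f1 >= f2) x1 else x2
    }
  }
  list(x = best_x, f = best_f)
}

#' Fit free parameters of a demographic model by composite likelihood
#'
#' Each of `n_starts` independent runs draws a starting point log-uniformly
#' within the declared ranges (uniformly for proportions) and refines it by
#' `n_cycles` sweeps of coordinate-wise golden-section search on the
#' (log-scaled) composite likelihood, with common random numbers across
#' evaluations so the objective is deterministic within a run.  The best
#' run is returned with the full per-start trajectory.
#'
#' @param model a `demographic_model` giving the topology and fixed values.
#' @param free list of [free_param()] declarations (may be empty, in which
#'   case only the likelihood of `model` is evaluated).
#' @param observed the observed [msfs].
#' @param n_starts,n_cycles,n_sims search effort: random starts, coordinate
#'   sweeps per start, simulated loci per likelihood evaluation.
#' @param seed integer seed.
#' @param golden_iter golden-section refinements per coordinate per sweep.
#' @param starts optional matrix of starting values (rows = starts) that
#'   overrides the random draw, e.g. to restart from earlier estimates.
#' @return a `fit_result`: `par`, `cl`, `model` (with estimates applied),
#'   `per_start` trajectory, `free`, settings and seed.
#' @export
fit_model <- function(model, free, observed, n_starts = 10, n_cycles = 10,
                      n_sims = 5000, seed = 1, golden_iter = 5,
                      starts = NULL) {
  model <- validate_model(model)
  sim_seed <- as.integer(seed %% .Machine$integer.max)
  obj <- cl_objective(model, free, observed, n_sims, sim_seed)
  k <- length(free)
  if (k == 0) {
    cl <- obj(numeric(0))
    return(structure(list(par = numeric(0), cl = cl, model = model,
                          per_start = data.frame(start = 1, cl = cl),
                          free = free, n_starts = 0, n_cycles = 0,
                          n_sims = n_sims, seed = seed,
                          obs_signature = obs_signature(observed)),
                     class = "fit_result"))
  }
  lower <- vapply(free, `[[`, numeric(1), "lower")
  upper <- vapply(free, `[[`, numeric(1), "upper")
  is_log <- vapply(free, `[[`, logical(1), "log")
  to_t <- function(x) ifelse(is_log, log(x), x)
  from_t <- function(z) ifelse(is_log, exp(z), z)
  set.seed(seed)
  if (is.null(starts)) {
    starts <- matrix(0, n_starts, k)
    for (s in seq_len(n_starts))
      starts[s, ] <- from_t(to_t(lower) +
                              runif(k) * (to_t(upper) - to_t(lower)))
  } else {
    starts <- matrix(starts, ncol = k)
    n_starts <- nrow(starts)
  }
  best <- NULL
  per_start <- data.frame(start = integer(0), cl = numeric(0))
  for (s in seq_len(n_starts)) {
    z <- to_t(pmin(pmax(starts[s, ], lower), upper))
    f_cur <- obj(from_t(z))
    for (cyc in seq_len(n_cycles)) {
      for (i in seq_len(k)) {
        fi <- function(zi) { zz <- z; zz[i] <- zi; obj(from_t(zz)) }
        g <- golden_max(fi, to_t(lower)[i], to_t(upper)[i],
                        iter = golden_iter)
        if (g$f >= f_cur) { z[i] <- g$x; f_cur <- g$f }
      }
    }
    per_start <- rbind(per_start, data.frame(start = s, cl = f_cur))
    if (is.null(best) || f_cur > best$cl)
      best <- list(par = from_t(z), cl = f_cur)
  }
  if (!is.finite(best$cl))
    stop("composite likelihood non-finite at every start; ",
         "check ranges against the model topology")
  names(best$par) <- vapply(free, `[[`, character(1), "name")
  structure(list(par = best$par, cl = best$cl,
                 model = validate_model(apply_params(model, free, best$par)),
                 per_start = per_start, free = free,
                 n_starts = n_starts, n_cycles = n_cycles, n_sims = n_sims,
                 seed = seed, obs_signature = obs_signature(observed)),
            class = "fit_result")
}

obs_signature <- function(observed) {
  c(entries = nrow(observed$idx), seg = sum(observed$counts),
    mono = observed$monomorphic, demes = length(observed$sample_sizes))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Composite-likelihood fit: CL =", format(x$cl, digits = 8), "\n")
  if (length(x$par)) print(round(x$par, 4))
  invisible(x)
}

#' Profile the composite likelihood over one parameter
#'
#' Evaluates the composite likelihood on a grid of one free parameter, all
#' other parameters held at their model values, with common random numbers
#' across grid points.  The Monte-Carlo error of a single likelihood
#' evaluation can exceed the local curvature of the profile, so the
#' likelihood at each grid value can be averaged over several independent
#' simulation seeds, and the reported estimate is read off a local
#' quadratic fit through the top of the averaged profile (`smooth_pts`
#' points around the grid maximum, skipping non-finite values); with
#' `smooth_pts = 0` the raw grid argmax is reported.
#'
#' @inheritParams fit_model
#' @param spec a single [free_param()].
#' @param grid numeric vector of parameter values to evaluate.
#' @param seeds one or more simulation seeds; the profile is the mean.
#' @param smooth_pts grid points on each side of the argmax used by the
#'   quadratic fit.
#' @return data.frame `value`, `cl`, with the profile estimate in
#'   `attr(, "estimate")` (clamped to the grid range).
#' @export
profile_composite_likelihood <- function(observed, model, spec, grid,
                                         n_sims = 10000, seeds = 1,
                                         smooth_pts = 3) {
  cls <- vapply(seeds, function(s) {
    obj <- cl_objective(model, list(spec), observed, n_sims,
                        as.integer(s %% .Machine$integer.max))
    vapply(grid, function(v) obj(v), numeric(1))
  }, numeric(length(grid)))
  cl <- rowMeans(matrix(cls, nrow = length(grid)))
  out <- data.frame(value = grid, cl = cl)
  i_max <- which.max(cl)
  est <- grid[i_max]
  if (smooth_pts > 0) {
    # fit only the contiguous run of top-ranked points around the argmax,
    # so cliffs (e.g. at an event-order change) cannot skew the vertex
    K <- 2 * smooth_pts + 1
    top <- order(-cl)[seq_len(min(K, sum(is.finite(cl))))]
    use <- i_max
    l <- i_max - 1
    while (l >= 1 && l %in% top) { use <- c(l, use); l <- l - 1 }
    r <- i_max + 1
    while (r <= length(grid) && r %in% top) { use <- c(use, r); r <- r + 1 }
    use <- use[is.finite(cl[use])]
    if (length(use) >= 3) {
      x <- grid[use]; y <- cl[use]
      fit <- stats::lm(y ~ x + I(x^2))
      b <- stats::coef(fit)
      if (is.finite(b[3]) && b[3] < 0) {
        vertex <- -b[2] / (2 * b[3])
        est <- min(max(vertex, min(grid)), max(grid))
      }
    }
  }
  attr(out, "estimate") <- est
  out
}

#' Rank fitted models by composite likelihood
#'
#' @param fits named list of `fit_result`s computed on the same observed
#'   MSFS with the same `n_sims`.
#' @return data.frame ranked by CL with `k` (free parameters),
#'   `AIC = 2k - 2 CL` and a `best` flag; ties keep input order.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  sigs <- vapply(fits, function(f) f$obs_signature, numeric(4))
  if (any(apply(sigs, 1, function(r) length(unique(r)) > 1)))
    stop("fits were computed on different observed spectra")
  if (length(unique(vapply(fits, `[[`, numeric(1), "n_sims"))) > 1)
    stop("fits used different n_sims; likelihoods are not comparable")
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  tab <- data.frame(model = nm,
                    k = vapply(fits, function(f) length(f$par), numeric(1)),
                    cl = vapply(fits, `[[`, numeric(1), "cl"))
  tab$AIC <- 2 * tab$k - 2 * tab$cl
  ord <- order(-tab$cl)
  tab <- tab[ord, , drop = FALSE]
  tab$best <- seq_len(nrow(tab)) == 1
  rownames(tab) <- NULL
  tab
}

#' Attach a new deme to a model by a split event
#'
#' @param model a `demographic_model`.
#' @param deme new deme name.
#' @param size its diploid effective size.
#' @param parent deme it splits from (backward merge target).
#' @param time split time in generations.
#' @export
attach_deme <- function(model, deme, size, parent, time) {
  if (deme %in% model$demes) stop("deme already present: ", deme)
  model$demes <- c(model$demes, deme)
  model$sizes <- c(model$sizes, stats::setNames(size, deme))
  model$events <- c(model$events, list(split_event(deme, parent, time)))
  validate_model(model)
}

#' Hierarchical model building: grow a demography one deme at a time
#'
#' Starting from a fitted backbone, each level attaches one new deme by
#' every candidate branch point (optionally with candidate admixture
#' pulses), refits every candidate with all parameters free (backbone
#' parameters are re-estimated at every level), and keeps the best by
#' composite likelihood before moving to the next level.
#'
#' @param observed_list one observed [msfs] per level, over the demes
#'   present at that level (in model deme order).
#' @param base_model,base_free backbone model and its free parameters.
#' @param levels list of levels; each level is a list with `deme` (name),
#'   `size_range` (2-vector), and `candidates`, a non-empty list of
#'   candidates: `list(parent =, time_range =, pulses = NULL)` where each
#'   pulse is `list(donor =, recipient =, time_range =, alpha_range =)`.
#' @inheritParams fit_model
#' @return list with the final `model`, final `fit` and per-level results
#'   (`fits`, comparison `table`, chosen candidate index).
#' @export
hierarchical_build <- function(observed_list, base_model, base_free, levels,
                               n_starts = 5, n_cycles = 3, n_sims = 2000,
                               seed = 1) {
  stopifnot(length(observed_list) == length(levels))
  model <- validate_model(base_model)
  free <- base_free
  out_levels <- list()
  fit <- NULL
  for (lvl in seq_along(levels)) {
    L <- levels[[lvl]]
    if (!length(L$candidates)) stop("level ", lvl, " has no candidates")
    fits <- list()
    cand_models <- list()
    for (ci in seq_along(L$candidates)) {
      cand <- L$candidates[[ci]]
      m2 <- attach_deme(model, L$deme, sqrt(prod(L$size_range)),
                        cand$parent, sqrt(prod(cand$time_range)))
      f2 <- c(free, list(
        free_param(paste0("N_", L$deme), "size", L$deme,
                   L$size_range[1], L$size_range[2]),
        free_param(paste0("T_", L$deme), "split_time", L$deme,
                   cand$time_range[1], cand$time_range[2])))
      for (pu in cand$pulses %||% list()) {
        m2$events <- c(m2$events, list(pulse_event(
          pu$donor, pu$recipient, mean(pu$alpha_range),
          sqrt(prod(pu$time_range)))))
        m2 <- validate_model(m2)
        tgt <- paste(pu$donor, pu$recipient, sep = ":")
        f2 <- c(f2, list(
          free_param(paste0("a_", tgt), "pulse_alpha", tgt,
                     pu$alpha_range[1], pu$alpha_range[2]),
          free_param(paste0("tp_", tgt), "pulse_time", tgt,
                     pu$time_range[1], pu$time_range[2])))
      }
      fits[[ci]] <- fit_model(m2, f2, observed_list[[lvl]],
                              n_starts = n_starts, n_cycles = n_cycles,
                              n_sims = n_sims, seed = seed + 97 * lvl + ci)
      cand_models[[ci]] <- list(model = m2, free = f2)
    }
    names(fits) <- paste0("parent_",
                          vapply(L$candidates, `[[`, "", "parent"),
                          "_c", seq_along(fits))
    tab <- compare_models(fits)
    best_i <- match(tab$model[1], names(fits))
    fit <- fits[[best_i]]
    model <- fit$model
    free <- cand_models[[best_i]]$free
    out_levels[[lvl]] <- list(fits = fits, table = tab, chosen = best_i)
  }
  list(model = model, fit = fit, levels = out_levels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parametric bootstrap confidence intervals
#'
#' Simulates `n_boot` spectra of the observed size under the fitted point
#' estimates; each replicate is refit from `n_opt` optimizations started at
#' the point estimates (jittered multiplicatively), keeping the best.
#' Confidence intervals are the 2.5/97.5 percentiles of the replicate
#' estimates (percentile intervals may exclude the point estimate; such
#' parameters are flagged).
#'
#' @param fit a `fit_result` with at least one free parameter.
#' @param observed the observed [msfs] the fit used (sets the replicate
#'   size).
#' @param n_boot bootstrap replicates.
#' @param n_opt optimizations per replicate.
#' @param n_cycles,n_sims,golden_iter refinement effort per optimization.
#' @param seed integer seed.
#' @param jitter relative log-scale jitter of the starting values.
#' @return a `bootstrap_ci`: data.frame per parameter with `point`,
#'   `lower`, `upper`, `covers_point`; replicate estimates in
#'   `attr(, "replicates")`; failed replicates are dropped with a warning
#'   when they exceed 10%.
#' @export
parametric_bootstrap <- function(fit, observed, n_boot = 50, n_opt = 15,
                                 n_cycles = 1, n_sims = 2000,
                                 golden_iter = 4, seed = 1, jitter = 0.1) {
  stopifnot(inherits(fit, "fit_result"), length(fit$par) >= 1)
  model <- fit$model
  L <- model$locus_length
  n_loci <- max(2, round((sum(observed$counts) + observed$monomorphic) / L))
  k <- length(fit$par)
  is_log <- vapply(fit$free, `[[`, logical(1), "log")
  lower <- vapply(fit$free, `[[`, numeric(1), "lower")
  upper <- vapply(fit$free, `[[`, numeric(1), "upper")
  reps <- matrix(NA_real_, n_boot, k,
                 dimnames = list(NULL, names(fit$par)))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    sim <- simulate_msfs(model, genes = observed$sample_sizes,
                         n_loci = n_loci, seed = seed + 7919 * b)
    set.seed(seed + b)
    starts <- t(vapply(seq_len(n_opt), function(o) {
      z <- ifelse(is_log, log(fit$par), fit$par) +
        stats::rnorm(k, 0, jitter) * ifelse(is_log, 1, pmax(fit$par, 0.05))
      pmin(pmax(ifelse(is_log, exp(z), z), lower), upper)
    }, numeric(k)))
    rb <- tryCatch(
      fit_model(model, fit$free, sim, n_cycles = n_cycles,
                n_sims = n_sims, seed = seed + 104729 * b,
                golden_iter = golden_iter, starts = starts),
      error = function(e) NULL)
    if (is.null(rb) || !is.finite(rb$cl)) failed <- failed + 1L
    else reps[b, ] <- rb$par
  }
  if (failed > 0.1 * n_boot)
    warning(failed, " of ", n_boot, " bootstrap replicates failed to fit")
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  ci <- data.frame(
    parameter = names(fit$par),
    point = unname(fit$par),
    lower = apply(reps, 2, stats::quantile, 0.025, names = FALSE),
    upper = apply(reps, 2, stats::quantile, 0.975, names = FALSE),
    n_boot = nrow(reps))
  ci$covers_point <- ci$point >= ci$lower & ci$point <= ci$upper
  attr(ci, "replicates") <- reps
  class(ci) <- c("bootstrap_ci", class(ci))
  ci
}

#' Down-sample every population to a fixed number of diploids
#'
#' Selects, per population, the `k` individuals with the most genotyped
#' sites (ties broken at random under `seed`), then drops every site with
#' any missing genotype among the selected individuals, so the result
#' always satisfies the no-missing-data precondition of
#' [msfs_from_genotypes()].
#'
#' @param g a [genotype_matrix].
#' @param k_per_pop diploids to keep per population.
#' @param seed integer seed for tie-breaking.
#' @export
downsample_genotypes <- function(g, k_per_pop, seed = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  set.seed(seed)
  keep <- unlist(lapply(unique(g$pops), function(p) {
    idx <- which(g$pops == p)
    if (length(idx) < k_per_pop)
      stop("population ", p, " has fewer than ", k_per_pop, " samples")
    complete <- rowSums(!is.na(g$geno[idx, , drop = FALSE]))
    idx[order(-complete, sample.int(length(idx)))][seq_len(k_per_pop)]
  }))
  g2 <- subset_genotypes(g, samples = sort(keep))
  full <- colSums(is.na(g2$geno)) == 0
  subset_genotypes(g2, sites = full)
}
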