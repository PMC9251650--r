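#' Backward-time demographic model
#'
#' A demographic model is a set of named demes with diploid effective sizes
#' and a time-ordered list of backward-time events: population splits (a
#' daughter deme merges into its parent), admixture pulses (an instantaneous
#' transfer of a fraction of a deme's ancestry from a donor deme) and
#' stepwise size changes.  Time is counted in generations before present.
#'
#' @param sizes named numeric vector of diploid effective sizes, one per deme.
#' @param events list of events built with [split_event()], [pulse_event()]
#'   and [size_event()].  Events are sorted by time; ties keep input order.
#' @param mutation_rate per-base, per-generation mutation rate.
#' @param generation_time generation time in years, used only to convert
#'   inferred times to calendar ages.
#' @param locus_length length in bp of one non-recombining locus.
#' @return an object of class `demographic_model`.
#' @examples
#' m <- demographic_model(
#'   sizes  = c(A = 10000, B = 5000),
#'   events = list(split_event("B", "A", 2000))
#' )
#' @export
demographic_model <- function(sizes, events = list(),
                              mutation_rate = 1e-8,
                              generation_time = 3.5,
                              locus_length = 142) {
  stopifnot(is.numeric(sizes), length(sizes) >= 1, !is.null(names(sizes)))
  if (anyDuplicated(names(sizes))) stop("duplicated deme names")
  if (any(sizes <= 0)) stop("all effective sizes must be positive")
  m <- structure(list(
    demes = names(sizes),
    sizes = sizes,
    events = events,
    mutation_rate = mutation_rate,
    generation_time = generation_time,
    locus_length = locus_length
  ), class = "demographic_model")
  validate_model(m)
}

#' @rdname demographic_model
#' @param deme,parent,donor,recipient deme names.
#' @param time event time in generations before present (> 0).
#' @export
split_event <- function(deme, parent, time) {
  list(type = "split", deme = deme, parent = parent, time = time)
}

#' @rdname demographic_model
#' @param alpha admixture proportion in `[0, 1]`: looking forward in time, a
#'   fraction `alpha` of the recipient deme's ancestry is replaced by
#'   migrants from the donor at `time`.
#' @export
pulse_event <- function(donor, recipient, alpha, time) {
  list(type = "pulse", donor = donor, recipient = recipient,
       alpha = alpha, time = time)
}

#' @rdname demographic_model
#' @param size new diploid effective size taken (backward in time) at `time`.
#' @export
size_event <- function(deme, size, time) {
  list(type = "size", deme = deme, size = size, time = time)
}

#' Validate a demographic model
#'
#' Checks that event times are positive, pulse proportions lie in `[0, 1]`,
#' every event refers to a deme that is still extant (backward in time) when
#' the event fires, and that exactly one ancestral deme remains after all
#' splits, so no lineage can be orphaned.  Events are returned sorted by
#' time.
#'
#' @param m a `demographic_model`.
#' @return the model with a normalized (time-sorted) event list.
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "demographic_model"))
  ev <- m$events
  if (length(ev)) {
    times <- vapply(ev, `[[`, numeric(1), "time")
    if (any(!is.finite(times)) || any(times <= 0))
      stop("event times must be positive and finite")
    ev <- ev[order(times)]
    alive <- m$demes
    for (e in ev) {
      if (e$type == "split") {
        if (!(e$deme %in% alive))
          stop("split of unknown or already-merged deme: ", e$deme)
        if (!(e$parent %in% alive))
          stop("split into unknown or already-merged deme: ", e$parent)
        if (e$deme == e$parent) stop("a deme cannot split into itself")
        alive <- setdiff(alive, e$deme)
      } else if (e$type == "pulse") {
        if (e$alpha < 0 || e$alpha > 1)
          stop("pulse proportion outside [0, 1]: ", e$alpha)
        for (d in c(e$donor, e$recipient))
          if (!(d %in% alive))
            stop("pulse involves a deme not extant at that time: ", d)
        if (e$donor == e$recipient) stop("pulse donor equals recipient")
      } else if (e$type == "size") {
        if (!(e$deme %in% alive))
          stop("size change on a deme not extant at that time: ", e$deme)
        if (e$size <= 0) stop("size change to non-positive size")
      } else stop("unknown event type: ", e$type)
    }
    if (length(alive) != 1)
      stop("after all events ", length(alive), " demes remain; ",
           "exactly one ancestral deme is required")
  } else if (length(m$demes) != 1) {
    stop("a model with several demes needs split events joining them")
  }
  m$events <- ev
  m
}

# Encode the event list as the numeric matrix the C++ engine consumes.
# Columns: time, type (1 split, 2 pulse, 3 size), a, b, param.
# Pulses are encoded backward: lineages in the recipient move to the donor
# with probability alpha.
encode_events <- function(m) {
  ev <- m$events
  out <- matrix(0, nrow = length(ev), ncol = 5)
  idx <- function(d) match(d, m$demes)
  for (i in seq_along(ev)) {
    e <- ev[[i]]
    out[i, 1] <- e$time
    if (e$type == "split") {
      out[i, 2:5] <- c(1, idx(e$deme), idx(e$parent), 0)
    } else if (e$type == "pulse") {
      out[i, 2:5] <- c(2, idx(e$recipient), idx(e$donor), e$alpha)
    } else {
      out[i, 2:5] <- c(3, idx(e$deme), 0, e$size)
    }
  }
  out
}

#' Convert generations to years and thousands of years
#'
#' @param t time in generations (non-negative).
#' @param generation_time generation time in years.
#' @return `generations_to_years()` returns years; `generations_to_ky()`
#'   rounds to the nearest thousand years for reporting.
#' @examples
#' generations_to_years(26247)         # 91864.5
#' generations_to_ky(26247)            # 92
#' @export
generations_to_years <- function(t, generation_time = 3.5) {
  stopifnot(all(t >= 0))
  t * generation_time
}

#' @rdname generations_to_years
#' @export
generations_to_ky <- function(t, generation_time = 3.5) {
  round(generations_to_years(t, generation_time) / 1000)
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model:", length(x$demes), "demes (",
      paste(x$demes, collapse = ", "), ")\n")
  cat("  mutation rate", format(x$mutation_rate), "per bp per generation;",
      "locus length", x$locus_length, "bp;",
      "generation time", x$generation_time, "y\n")
  for (e in x$events) {
    if (e$type == "split")
      cat(sprintf("  t=%8.0f  split  %s -> %s\n", e$time, e$deme, e$parent))
    else if (e$type == "pulse")
      cat(sprintf("  t=%8.0f  pulse  %s -> %s (alpha=%.2f)\n",
                  e$time, e$donor, e$recipient, e$alpha))
    else
      cat(sprintf("  t=%8.0f  size   %s = %.0f\n", e$time, e$deme, e$size))
  }
  invisible(x)
}
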