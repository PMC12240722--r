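# Exogenous presentation schedules: which of the two items is on screen
# (and hence sampled) at each time step. Items alternate; one item is
# assigned the long-duration distribution and the other the short one.

#' Generate an alternating presentation schedule
#'
#' Items alternate on screen until the deadline. Each presentation segment's
#' duration is drawn from the item's distribution: long presentations have
#' mean 500 ms (SD 100), short presentations mean 200 ms (SD 50). Draws are
#' truncated below at `dt_ms` and rounded to the nearest multiple of
#' `dt_ms`, so each segment maps to a whole number of samples. Segments are
#' appended until the cumulative duration covers the deadline; the unused
#' tail of the last segment is simply never reached on trials that stop
#' early.
#'
#' @param long_item Index (1 or 2) of the item drawn from the long-duration
#'   distribution.
#' @param first_item Index of the item shown first. Independent of
#'   `long_item`.
#' @param dt_ms Sample duration in ms.
#' @param deadline_ms Response deadline in ms.
#' @param long_mean,long_sd,short_mean,short_sd Presentation-duration
#'   distribution parameters in ms.
#' @return An object of class `presentation_schedule` with a `segments`
#'   data frame (`item_index`, `duration_ms`) and the generating settings.
#' @export
generate_schedule <- function(long_item = 1L, first_item = 1L,
                              dt_ms = 10, deadline_ms = 5000,
                              long_mean = 500, long_sd = 100,
                              short_mean = 200, short_sd = 50) {
  stopifnot(long_item %in% 1:2, first_item %in% 1:2,
            long_mean > 0, short_mean > 0, dt_ms > 0, deadline_ms >= dt_ms)
  item <- integer(0); dur <- numeric(0)
  # draw alternating segments in blocks until the deadline is covered
  block <- ceiling(deadline_ms / (min(long_mean, short_mean) / 2)) + 2L
  while (sum(dur) < deadline_ms) {
    nxt <- if (length(item)) 3L - item[length(item)] else as.integer(first_item)
    it <- rep_len(c(nxt, 3L - nxt), block)
    m <- ifelse(it == long_item, long_mean, short_mean)
    s <- ifelse(it == long_item, long_sd, short_sd)
    d <- pmax(dt_ms, round(rnorm(block, m, s) / dt_ms) * dt_ms)
    item <- c(item, it); dur <- c(dur, d)
  }
  keep <- seq_len(which(cumsum(dur) >= deadline_ms)[1])
  item <- item[keep]; dur <- dur[keep]
  structure(list(
    segments = structure(list(item_index = item, duration_ms = dur),
                         class = "data.frame",
                         row.names = seq_along(item)),
    long_item = as.integer(long_item), first_item = as.integer(first_item),
    dt_ms = dt_ms, deadline_ms = deadline_ms,
    long_mean = long_mean, short_mean = short_mean
  ), class = "presentation_schedule")
}

#' Per-step attention sequence of a schedule
#'
#' Expands a schedule into the item attended at each sample step, up to
#' `n_steps` (default: the full deadline). Step `t` covers the half-open
#' time interval `[(t-1) * dt_ms, t * dt_ms)`.
#'
#' @param schedule A `presentation_schedule`.
#' @param n_steps Number of steps to expand.
#' @return Integer vector of item indices, length `n_steps`.
#' @export
attended_steps <- function(schedule,
                           n_steps = as.integer(schedule$deadline_ms / schedule$dt_ms)) {
  steps <- rep(schedule$segments$item_index,
               times = schedule$segments$duration_ms / schedule$dt_ms)
  if (length(steps) < n_steps)
    stop("out of range: schedule does not cover ", n_steps, " steps")
  steps[seq_len(n_steps)]
}

#' Item attended at a given sample step
#'
#' @param schedule A `presentation_schedule`.
#' @param step Sample index, >= 1.
#' @return The item index on screen during step `step`.
#' @export
attended_at <- function(schedule, step) {
  if (step < 1 || step * schedule$dt_ms > sum(schedule$segments$duration_ms))
    stop("out of range: step ", step, " beyond schedule")
  attended_steps(schedule, step)[step]
}

#' Expected share of presentation time for an item
#'
#' The fraction of screen time allotted to an item, computed from the
#' presentation-duration distribution means (not the realized draws): the
#' long item receives `long_mean / (long_mean + short_mean)`. This is the
#' future-allocation assumption the stopping rule uses when it projects how
#' additional samples would be split between the items.
#'
#' @param schedule A `presentation_schedule`.
#' @param item_index Item (1 or 2).
#' @return Fraction in `[0, 1]`; the two items' shares sum to 1.
#' @export
duration_share <- function(schedule, item_index) {
  stopifnot(item_index %in% 1:2)
  tot <- schedule$long_mean + schedule$short_mean
  if (item_index == schedule$long_item) schedule$long_mean / tot
  else schedule$short_mean / tot
}
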