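#' Construct a population-activity object
#'
#' The central data container: trial-averaged firing rates of a neural
#' population as a 3-D array (neurons x conditions x time) with a uniform
#' time axis (ms, relative to the go cue) and named event markers. All
#' analysis functions ([jpca()], [cmpt()], [fit_preferred_directions()], ...)
#' consume this object, so externally recorded data can be analyzed by
#' wrapping it with this constructor.
#'
#' @param rates Numeric array, neurons x conditions x time; all finite.
#' @param time_ms Time axis in ms (uniform spacing), length `dim(rates)[3]`.
#' @param events Named numeric vector of time markers (e.g. `go_cue`,
#'   `neural_movement_onset`, `movement_end`), each within the time axis.
#' @param neuron_meta Optional data.frame of per-neuron ground truth
#'   (e.g. latency `tau`, preferred angle `theta`).
#' @param condition_meta Optional data.frame of per-condition metadata
#'   (e.g. `target_angle`).
#' @param generator Character tag naming the generating model.
#' @return Object of class `population_activity`.
#' @export
population_activity <- function(rates, time_ms, events = c(go_cue = 0),
                                neuron_meta = NULL, condition_meta = NULL,
                                generator = "user") {
  rates <- unname(rates)
  if (length(dim(rates)) != 3L) stop("`rates` must be a 3-D array: neurons x conditions x time")
  if (!all(is.finite(rates))) stop("`rates` must be finite")
  if (length(time_ms) != dim(rates)[3]) stop("`time_ms` length must match dim(rates)[3]")
  dt <- diff(time_ms)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-8 * abs(dt[1]))
    stop("`time_ms` must be uniformly spaced")
  if (length(events)) {
    if (is.null(names(events)) || any(!nzchar(names(events)))) stop("`events` must be named")
    lo <- min(time_ms) - (dt[1] %||% 0); hi <- max(time_ms) + (dt[1] %||% 0)
    if (any(events < lo | events > hi)) stop("events must lie within the time axis")
  }
  structure(
    list(rates = rates, time_ms = as.numeric(time_ms),
         dt = if (length(dt)) dt[1] else NA_real_,
         events = events, neuron_meta = neuron_meta,
         condition_meta = condition_meta, generator = generator),
    class = "population_activity"
  )
}

#' @export
print.population_activity <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("Population activity [%s]: %d neurons, %d conditions, %d samples (%g..%g ms, dt = %g)\n",
              x$generator, d[1], d[2], d[3], min(x$time_ms), max(x$time_ms), x$dt))
  if (length(x$events))
    cat("  events:", paste(sprintf("%s = %g", names(x$events), x$events), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.population_activity <- function(x) dim(x$rates)

# Indices of the time axis falling in [window[1], window[2]] (inclusive,
# with half-sample slack so that endpoints on the grid are kept).
window_index <- function(pop, window) {
  eps <- pop$dt / 2
  idx <- which(pop$time_ms >= window[1] - eps & pop$time_ms <= window[2] + eps)
  if (length(idx) < 2L) stop("analysis window contains fewer than 2 samples")
  idx
}

# n x (c*t) matrix over a time window; condition blocks are contiguous
# (columns ordered condition-major: all times of condition 1, then 2, ...).
flatten_rates <- function(pop, window = NULL) {
  idx <- if (is.null(window)) seq_along(pop$time_ms) else window_index(pop, window)
  d <- dim(pop$rates)
  m <- matrix(pop$rates[, , idx, drop = FALSE], nrow = d[1])
  # array slicing gives neuron x (cond fast, time slow); reorder to cond blocks
  nt <- length(idx)
  ord <- as.vector(outer(seq_len(nt), seq_len(d[2]), function(t, c) (t - 1L) * d[2] + c))
  m[, ord, drop = FALSE]
}

#' Take a neuron/condition subset of a population
#'
#' @param pop A `population_activity`.
#' @param neurons,conditions Integer index vectors (default: all).
#' @return A `population_activity` restricted to the requested rows.
#' @export
subset_population <- function(pop, neurons = NULL, conditions = NULL) {
  stopifnot(inherits(pop, "population_activity"))
  d <- dim(pop$rates)
  neurons <- neurons %||% seq_len(d[1])
  conditions <- conditions %||% seq_len(d[2])
  population_activity(
    pop$rates[neurons, conditions, , drop = FALSE], pop$time_ms, pop$events,
    if (!is.null(pop$neuron_meta)) pop$neuron_meta[neurons, , drop = FALSE],
    if (!is.null(pop$condition_meta)) pop$condition_meta[conditions, , drop = FALSE],
    pop$generator
  )
}
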