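#' Influx configuration for the two kinesin species
#'
#' Motors arrive at the minus end of the bundle with Gaussian-distributed
#' inter-arrival times.  Rates are literal motors per second per species.
#'
#' @param rate_a Arrival rate of the fast species (motors/s).
#' @param rate_b Arrival rate of the slow species (motors/s).
#' @param mode `"continuous"` (arrivals over the whole run) or `"pulsed"`
#'   (arrivals only during the first `pulse_duration_s` seconds).
#' @param pulse_duration_s Pulse length in seconds (pulsed mode; default 15).
#' @param drop_blocked_arrivals If `TRUE`, an arrival that finds no free
#'   loading site is discarded instead of queueing for retry.  The default
#'   (`FALSE`) queues blocked arrivals FIFO so that motor counts are
#'   conserved in pulsed-clearance experiments.
#' @return An object of class `influx_config`.
#' @export
influx_config <- function(rate_a = 10, rate_b = 10,
                          mode = c("continuous", "pulsed"),
                          pulse_duration_s = 15,
                          drop_blocked_arrivals = FALSE) {
  mode <- match.arg(mode)
  if (rate_a < 0 || rate_b < 0) stop("rates must be >= 0")
  if (mode == "pulsed" && pulse_duration_s < 0)
    stop("pulse_duration_s must be >= 0 in pulsed mode")
  structure(
    list(rate_a = rate_a, rate_b = rate_b, mode = mode,
         pulse_duration_s = pulse_duration_s,
         drop_blocked_arrivals = isTRUE(drop_blocked_arrivals)),
    class = "influx_config")
}

# Gaussian inter-arrival gaps in iterations: mean mu = 1/(rate * dt),
# sd = mu/3, clamped to >= 1 iteration and rounded to the nearest integer.
arrival_iters <- function(rate, horizon_iters, dt_s) {
  if (rate <= 0 || horizon_iters < 1) return(integer(0))
  mu <- 1 / (rate * dt_s)
  # draw enough gaps to cover the horizon, topping up if needed
  out <- integer(0)
  last <- 0
  while (last <= horizon_iters) {
    n <- max(16L, ceiling(1.3 * (horizon_iters - last) / mu) + 16L)
    gaps <- round_half_up(pmax(1, rnorm(n, mean = mu, sd = mu / 3)))
    it <- last + cumsum(gaps)
    out <- c(out, it)
    last <- it[length(it)]
  }
  as.integer(out[out <= horizon_iters])
}

#' Draw per-species arrival schedules
#'
#' Uses the current R random number stream; wrap in `set.seed()` for
#' reproducibility.  In pulsed mode no arrival falls after the pulse.
#'
#' @param config An [influx_config()].
#' @param horizon_iters Number of iterations in the run.
#' @param dt_s Iteration duration in seconds.
#' @return A list of class `arrival_schedule` with integer vectors `a` and
#'   `b` of arrival iterations (non-decreasing, gaps >= 1).
#' @export
make_schedule <- function(config, horizon_iters, dt_s = 0.04) {
  stopifnot(inherits(config, "influx_config"), horizon_iters >= 0)
  lim <- horizon_iters
  if (config$mode == "pulsed")
    lim <- min(lim, seconds_to_iterations(config$pulse_duration_s, dt_s))
  structure(
    list(a = arrival_iters(config$rate_a, lim, dt_s),
         b = arrival_iters(config$rate_b, lim, dt_s)),
    class = "arrival_schedule")
}

#' @export
print.influx_config <- function(x, ...) {
  cat(sprintf("<influx_config> fast %g/s, slow %g/s, %s%s\n",
              x$rate_a, x$rate_b, x$mode,
              if (x$mode == "pulsed")
                sprintf(" (%g s pulse)", x$pulse_duration_s) else ""))
  invisible(x)
}
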