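#' Construct a bundle-segment scenario specification
#'
#' Low-level constructor.  A scenario is a lattice geometry plus a per-site
#' accessibility mask (FALSE = blocked by staggering, damage or bound
#' proteins), behavioural switches and reservoir settings.  Use
#' [build_scenario()] for the eight canonical injury scenarios.
#'
#' @param geometry A [lattice_geometry()].
#' @param accessible Logical matrix (`n_lanes` x `n_sites`); `TRUE` where a
#'   motor may bind.  Defaults to fully accessible.
#' @param lateral_allowed May motors change lanes when blocked?
#' @param stagger_fraction Fraction of each non-channel lane blocked
#'   (0, 0.125, 0.25 or 0.5 for the canonical scenarios).
#' @param stagger_end `"none"`, `"proximal"` (minus end) or `"distal"`
#'   (plus end).
#' @param channel_lane Index of the always-open lane (default: middle lane).
#' @param reservoir_capacity Motor capacity of each per-site productive
#'   reservoir (default 50).
#' @param atp_zones Optional list of ATP-depleted zones, each a list with
#'   fields `lanes`, `site_start`, `site_end`; motors detaching in a zone
#'   must wait `atp_wait_s` in the reservoir before reattachment.
#' @param atp_wait_s Minimum reservoir residence in ATP-depleted zones
#'   (default 10 s = 250 iterations).
#' @param scenario_id Optional canonical scenario id (1..8).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(geometry = lattice_geometry(), accessible = NULL,
                          lateral_allowed = TRUE, stagger_fraction = 0,
                          stagger_end = c("none", "proximal", "distal"),
                          channel_lane = NULL, reservoir_capacity = 50,
                          atp_zones = NULL, atp_wait_s = 10,
                          scenario_id = NA_integer_) {
  stagger_end <- match.arg(stagger_end)
  T <- geometry$n_lanes
  N <- geometry$n_sites
  if (is.null(channel_lane)) channel_lane <- (T + 1L) %/% 2L
  if (is.null(accessible)) accessible <- matrix(TRUE, T, N)
  stopifnot(is.matrix(accessible), nrow(accessible) == T, ncol(accessible) == N)
  atp_wait <- matrix(0L, T, N)
  if (!is.null(atp_zones)) {
    wt <- seconds_to_iterations(atp_wait_s, geometry$dt_s)
    for (z in atp_zones)
      atp_wait[z$lanes, seq(z$site_start, z$site_end)] <- wt
  }
  structure(
    list(geometry = geometry, accessible = accessible,
         lateral_allowed = isTRUE(lateral_allowed),
         stagger_fraction = stagger_fraction, stagger_end = stagger_end,
         channel_lane = as.integer(channel_lane),
         reservoir_capacity = as.integer(reservoir_capacity),
         atp_wait = atp_wait, atp_wait_s = atp_wait_s,
         scenario_id = as.integer(scenario_id)),
    class = "scenario_spec")
}

#' Build one of the eight canonical injury scenarios
#'
#' Scenario 1: fully accessible lattice with lateral movement.
#' Scenario 2: fully accessible, lateral movement forbidden.
#' Scenarios 3/4/5: 12.5/25/50% proximal (minus-end) staggering of every
#' lane except the channel lane; 12.5% is within normal variation, 25% and
#' 50% model increasingly severe injury.
#' Scenarios 6/7/8: the same fractions staggered at the distal (plus) end.
#' Blocked-site counts are `round_half_up(fraction * n_sites)` per lane.
#'
#' @param scenario_id Integer 1..8.
#' @param geometry A [lattice_geometry()].
#' @param channel_lane The always-open lane (default: middle lane).
#' @param ... Further arguments passed to [scenario_spec()]
#'   (e.g. `reservoir_capacity`, `atp_zones`).
#' @return A `scenario_spec`.
#' @examples
#' sc <- build_scenario(4)
#' sum(!sc$accessible)  # 250 blocked sites: 125 on each non-channel lane
#' @export
build_scenario <- function(scenario_id, geometry = lattice_geometry(),
                           channel_lane = NULL, ...) {
  scenario_id <- as.integer(scenario_id)
  if (!scenario_id %in% 1:8) stop("scenario_id must be in 1..8")
  T <- geometry$n_lanes
  N <- geometry$n_sites
  if (is.null(channel_lane)) channel_lane <- (T + 1L) %/% 2L
  frac <- c(0, 0, 0.125, 0.25, 0.5, 0.125, 0.25, 0.5)[scenario_id]
  end <- c("none", "none", "proximal", "proximal", "proximal",
           "distal", "distal", "distal")[scenario_id]
  acc <- matrix(TRUE, T, N)
  if (frac > 0) {
    k <- round_half_up(frac * N)
    blocked_sites <- if (end == "proximal") seq_len(k) else seq(N - k + 1, N)
    acc[setdiff(seq_len(T), channel_lane), blocked_sites] <- FALSE
  }
  scenario_spec(geometry = geometry, accessible = acc,
                lateral_allowed = scenario_id != 2L,
                stagger_fraction = frac, stagger_end = end,
                channel_lane = channel_lane, scenario_id = scenario_id, ...)
}

#' @export
print.scenario_spec <- function(x, ...) {
  g <- x$geometry
  cat(sprintf(
    "<scenario_spec>%s %d lanes x %d sites, %d blocked site(s) (%s %g%%), lateral %s, reservoir capacity %d\n",
    if (is.na(x$scenario_id)) "" else sprintf(" [scenario %d]", x$scenario_id),
    g$n_lanes, g$n_sites, sum(!x$accessible), x$stagger_end,
    100 * x$stagger_fraction, if (x$lateral_allowed) "on" else "off",
    x$reservoir_capacity))
  invisible(x)
}

#' Count consecutive empty accessible sites ahead of a motor
#'
#' Scans sites `site + 1, site + 2, ...` along the motor's lane and counts
#' how many are accessible and empty before the first occupied or blocked
#' site (or the lattice end).
#'
#' @param scenario A `scenario_spec`.
#' @param occupancy Logical matrix (`n_lanes` x `n_sites`): `TRUE` where a
#'   motor is present.
#' @param lane,site Position of the motor to query (1-based; site 1 is the
#'   minus end).
#' @return Integer gap size (>= 0).
#' @export
gap_ahead <- function(scenario, occupancy, lane, site) {
  N <- scenario$geometry$n_sites
  if (!isTRUE(occupancy[lane, site])) stop("query site is not occupied")
  g <- 0L
  j <- site + 1L
  while (j <= N && scenario$accessible[lane, j] && !occupancy[lane, j]) {
    g <- g + 1L
    j <- j + 1L
  }
  g
}
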