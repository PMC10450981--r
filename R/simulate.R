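#' Specification of a linked multi-segment axon
#'
#' Chains bundle segments end to end: motors delivered at a segment's plus
#' end enter a junction reservoir from which the next segment loads them.
#' Names follow the convention `"1-4P-7D"`: segment scenario ids separated
#' by dashes, with optional `P`/`D` annotations for proximal/distal
#' staggering (the annotations are informative only; the scenario id
#' determines the geometry).
#'
#' @param name Chain name such as `"1-4P-7D"`, or `NULL` if `sections` is
#'   given directly.
#' @param geometry Shared [lattice_geometry()] for all segments.
#' @param sections Optional list of `scenario_spec` objects (overrides
#'   `name`).
#' @param ... Passed to [build_scenario()] for each segment.
#' @return An object of class `multi_mmls_spec`.
#' @examples
#' multi_mmls_spec("1-4P-7D")
#' @export
multi_mmls_spec <- function(name = NULL, geometry = lattice_geometry(),
                            sections = NULL, ...) {
  if (is.null(sections)) {
    if (is.null(name)) stop("give either a chain name or a section list")
    ids <- parse_chain_name(name)
    sections <- lapply(ids, build_scenario, geometry = geometry, ...)
  } else {
    stopifnot(all(vapply(sections, inherits, TRUE, "scenario_spec")))
    if (is.null(name))
      name <- paste(vapply(sections, function(s) as.character(s$scenario_id),
                           ""), collapse = "-")
  }
  if (length(sections) < 1) stop("need at least one section")
  structure(list(name = name, sections = sections, geometry = geometry),
            class = "multi_mmls_spec")
}

parse_chain_name <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  ids <- suppressWarnings(as.integer(sub("([0-9]+)[PDpd]?$", "\\1", parts)))
  if (any(is.na(ids)) || !all(ids %in% 1:8))
    stop("cannot parse chain name: ", name)
  ids
}

#' @export
print.multi_mmls_spec <- function(x, ...) {
  cat(sprintf("<multi_mmls_spec> %s (%d section(s), %d lanes x %d sites each)\n",
              x$name, length(x$sections), x$geometry$n_lanes,
              x$geometry$n_sites))
  invisible(x)
}

#' Randomly pre-populate a segment with motors
#'
#' Emulates residual ("sprinkled") traffic left on the lattice by earlier
#' transport: each accessible site is occupied independently with
#' probability `density`, with an even species split and zero accumulated
#' run length.
#'
#' @param scenario A `scenario_spec`.
#' @param density Occupation probability per accessible site (default 0.1).
#' @param p_fast Probability that an occupying motor is the fast species.
#' @return Integer matrix with columns lane, site, species (1 = fast,
#'   2 = slow), suitable for the `initial` argument of [run_multi()].
#' @export
sprinkle_occupancy <- function(scenario, density = 0.1, p_fast = 0.5) {
  acc <- which(scenario$accessible, arr.ind = TRUE)
  keep <- stats::runif(nrow(acc)) < density
  acc <- acc[keep, , drop = FALSE]
  sp <- ifelse(stats::runif(nrow(acc)) < p_fast, 1L, 2L)
  cbind(lane = acc[, 1], site = acc[, 2], species = sp)
}

#' Simulate a linked multi-segment axon
#'
#' Runs the full iteration loop -- influx, TASEP sweep, reservoir
#' kinetics, delivery -- synchronously for every segment.
#' Segment 1 receives external influx; each later segment loads from the
#' upstream junction reservoir at the combined configured rate with FIFO
#' queue-retry semantics.
#'
#' @param spec A [multi_mmls_spec()] (or a single `scenario_spec`).
#' @param influx An [influx_config()].
#' @param species Species list as returned by [default_species()].
#' @param horizon_s Observation time in seconds (default 600).
#' @param seed Optional integer seed (calls `set.seed()`).
#' @param sprinkle_density If > 0, every segment is pre-populated with this
#'   occupancy density before the run.
#' @param initial Explicit initial occupancy instead of sprinkling: a matrix
#'   with columns lane, site, species (single segment) or a list of such
#'   matrices, one per segment.
#' @param stop_when_empty Stop as soon as no motor remains queued, on a
#'   lattice, in a reservoir or in an intermediate junction (used for
#'   pulsed-clearance runs).
#' @param crowding_detach If `FALSE`, motors blocked with no lateral escape
#'   stall in place instead of detaching (used for the plain-TASEP
#'   validation limit).
#' @param exit_prob Probability that a delivery-eligible motor actually
#'   exits per iteration (default 1; < 1 only in the validation limit).
#' @param update_order Sweep order over motors within an iteration.
#'   `"ascending"` (default) visits sites minus-end-first with a
#'   once-per-iteration guard, so trailing motors see leaders that have not
#'   yet moved -- congestion can form, which is essential for the injury
#'   phenomenology.  `"descending"` visits plus-end-first (vacancies opened
#'   ahead are visible immediately; platoons move cohesively and almost
#'   never jam) and `"shuffle"` visits motors in random order; both are
#'   provided for sensitivity analysis.
#' @param lateral_target `"displaced"` (lane change lands at site + v,
#'   default) or `"nearest"` (lands at site +/- 1 of the adjacent lane).
#' @param snapshot_every Iterations between ledger/invariant audits
#'   (default 1000; 0 disables).
#' @param burn_in_s Seconds excluded from the time-averaged density profile.
#' @return An object of class `mmls_run`; see Details.
#' @details The returned object carries, per section: `outflow` (iteration x
#'   lane x species delivery counts), `detach_counts` (lane x site x species
#'   x cause), `reattach_counts` (lane x site x species), `detach_series`
#'   (iteration x species x cause), `density` (lane x site x species
#'   time-averaged occupancy) and a `totals` ledger.  Global fields include
#'   the created-motor counts, snapshot audits and, for pulsed runs, the
#'   clearance time.
#' @export
run_multi <- function(spec, influx = influx_config(),
                      species = NULL, horizon_s = 600, seed = NULL,
                      sprinkle_density = 0, initial = NULL,
                      stop_when_empty = FALSE,
                      crowding_detach = TRUE, exit_prob = 1,
                      update_order = c("ascending", "descending", "shuffle"),
                      lateral_target = c("displaced", "nearest"),
                      snapshot_every = 1000, burn_in_s = 0) {
  if (inherits(spec, "scenario_spec"))
    spec <- multi_mmls_spec(sections = list(spec), geometry = spec$geometry)
  stopifnot(inherits(spec, "multi_mmls_spec"), inherits(influx, "influx_config"))
  update_order <- match.arg(update_order)
  lateral_target <- match.arg(lateral_target)
  if (!is.null(seed)) set.seed(seed)
  geo <- spec$geometry
  if (is.null(species)) species <- default_species(geo)
  H <- seconds_to_iterations(horizon_s, geo$dt_s)
  S <- length(spec$sections)

  sched <- make_schedule(influx, H, geo$dt_s)
  transfer <- vector("list", S)
  if (S > 1) {
    combined <- influx$rate_a + influx$rate_b
    for (si in 2:S) transfer[[si]] <- arrival_iters(combined, H, geo$dt_s)
  }
  if (is.null(initial)) {
    initial <- vector("list", S)
    if (sprinkle_density > 0)
      initial <- lapply(spec$sections, sprinkle_occupancy,
                        density = sprinkle_density)
  } else {
    if (is.matrix(initial)) initial <- list(initial)
    stopifnot(length(initial) == S)
    initial <- lapply(initial, function(m) {
      if (!is.null(m)) storage.mode(m) <- "integer"
      m
    })
  }

  sections_cfg <- lapply(spec$sections, function(s) {
    acc <- s$accessible
    storage.mode(acc) <- "integer"
    list(accessible = acc, lateral = s$lateral_allowed,
         atp_wait = s$atp_wait, capacity = s$reservoir_capacity)
  })
  opts <- list(
    crowding_detach = isTRUE(crowding_detach),
    drop_blocked = influx$drop_blocked_arrivals,
    stop_when_empty = isTRUE(stop_when_empty),
    record_density = TRUE,
    exit_prob = exit_prob,
    update_order = c(descending = 0L, shuffle = 1L, ascending = 2L)[[update_order]],
    lateral_target = if (lateral_target == "displaced") 0L else 1L,
    snapshot_every = as.integer(snapshot_every),
    burn_in = seconds_to_iterations(burn_in_s, geo$dt_s))

  raw <- engine_run(sections_cfg, species_table(species), sched$a, sched$b,
                    transfer, initial, H, opts)

  sp_names <- c(species$fast$name, species$slow$name)
  cause_names <- c("crowding", "processivity")
  dens_iters <- max(raw$iters_run - opts$burn_in, 1L)
  sections <- lapply(raw$sections, function(rs) {
    N <- geo$n_sites; T <- geo$n_lanes
    detach <- aperm(array(rs$detach_counts, c(2, 2, N, T)), c(4, 3, 2, 1))
    dimnames(detach) <- list(NULL, NULL, sp_names, cause_names)
    reatt <- aperm(array(rs$reattach_counts, c(2, N, T)), c(3, 2, 1))
    dimnames(reatt) <- list(NULL, NULL, sp_names)
    ofl <- aperm(array(rs$outflow, c(2, T, H)), c(3, 2, 1))
    dimnames(ofl) <- list(NULL, NULL, sp_names)
    dser <- aperm(array(rs$detach_series, c(2, 2, H)), c(3, 2, 1))
    dimnames(dser) <- list(NULL, sp_names, cause_names)
    dens <- aperm(array(rs$density_sum, c(2, N, T)), c(3, 2, 1)) / dens_iters
    dimnames(dens) <- list(NULL, NULL, sp_names)
    list(outflow = ofl, detach_counts = detach, reattach_counts = reatt,
         detach_series = dser, density = dens,
         totals = c(loaded = rs$loaded, delivered = rs$delivered,
                    leaked = rs$leaked, transferred_in = rs$transferred_in,
                    queued = rs$queued, junction = rs$junction,
                    in_reservoirs = rs$in_reservoirs))
  })

  snaps <- as.data.frame(raw$snapshots)
  names(snaps) <- c("iter", "created", "queued", "on_lattice", "in_reservoir",
                    "delivered", "leaked", "in_junction", "dropped")
  motors <- raw$motors
  motors$species <- sp_names[motors$species]
  motors$status <- c("queued", "on_lattice", "in_reservoir", "delivered",
                     "leaked", "in_junction", "dropped")[motors$status + 1L]

  clearance_iter <- raw$clearance_iter
  clearance_s <- if (clearance_iter < 0) NA_real_ else clearance_iter * geo$dt_s
  if (sum(raw$created) == 0) clearance_s <- 0

  structure(
    list(spec = spec, influx = influx, species = species,
         horizon_s = horizon_s, dt_s = geo$dt_s, n_iters = H,
         iters_run = raw$iters_run, seed = seed,
         sections = sections,
         created = c(fast = raw$created[1], slow = raw$created[2]),
         dropped = raw$dropped,
         clearance_iter = clearance_iter, clearance_s = clearance_s,
         snapshots = snaps, snapshot_ok = raw$snapshot_ok,
         motors = motors),
    class = "mmls_run")
}

#' Simulate a single bundle segment
#'
#' Convenience wrapper around [run_multi()] for one scenario; identical
#' results to a one-section chain under the same seed.
#'
#' @inheritParams run_multi
#' @param scenario A `scenario_spec` (see [build_scenario()]).
#' @param ... Passed on to [run_multi()].
#' @return An `mmls_run` with a single section.
#' @export
run_simulation <- function(scenario, influx = influx_config(),
                           species = NULL, horizon_s = 600, seed = NULL, ...) {
  stopifnot(inherits(scenario, "scenario_spec"))
  run_multi(scenario, influx = influx, species = species,
            horizon_s = horizon_s, seed = seed, ...)
}

#' Time for a pulsed input to clear a multi-segment axon
#'
#' Injects a pulse of motors and reports the time (seconds from pulse
#' start) at which no motor remains queued, bound, in a reservoir or in an
#' intermediate junction anywhere in the chain.  Leaked motors count as
#' exited.
#'
#' @inheritParams run_multi
#' @param ... Passed on to [run_multi()].
#' @return Clearance time in seconds, or `NA` (with attribute `"partial"`
#'   holding the end-of-run ledger) if the system did not empty within
#'   `horizon_s`.
#' @export
pulsed_clearance_time <- function(spec, influx, species = NULL,
                                  horizon_s = 600, seed = NULL,
                                  sprinkle_density = 0, ...) {
  if (influx$mode != "pulsed") stop("pulsed_clearance_time needs pulsed influx")
  run <- run_multi(spec, influx = influx, species = species,
                   horizon_s = horizon_s, seed = seed,
                   sprinkle_density = sprinkle_density,
                   stop_when_empty = TRUE, ...)
  out <- run$clearance_s
  if (is.na(out)) {
    warning("system did not clear within the horizon")
    attr(out, "partial") <- table(run$motors$status)
  }
  out
}

#' @export
print.mmls_run <- function(x, ...) {
  cat(sprintf("<mmls_run> %s: %g s (%d iters run), influx %g + %g motors/s (%s)\n",
              x$spec$name, x$horizon_s, x$iters_run, x$influx$rate_a,
              x$influx$rate_b, x$influx$mode))
  cat(sprintf("  motors created: %g fast + %g slow; dropped %g\n",
              x$created[["fast"]], x$created[["slow"]], x$dropped))
  for (si in seq_along(x$sections)) {
    tt <- x$sections[[si]]$totals
    cat(sprintf("  section %d: loaded %g, delivered %g, leaked %g, in reservoirs %g, junction %g\n",
                si, tt[["loaded"]], tt[["delivered"]], tt[["leaked"]],
                tt[["in_reservoirs"]], tt[["junction"]]))
  }
  if (!is.na(x$clearance_s))
    cat(sprintf("  clearance: %g s\n", x$clearance_s))
  invisible(x)
}
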