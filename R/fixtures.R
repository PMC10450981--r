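#' Canonical run configurations
#'
#' The factorial set of study conditions: the eight single-segment
#' scenarios and the six canonical three-segment chains, each at influx 10
#' and 15 motors/s per species, on the default 3 x 500 lattice.
#'
#' @return Data frame with columns `kind` ("single" or "multi"), `name`
#'   (scenario id or chain name) and `rate` (motors/s per species).
#' @export
fixture_scenarios <- function() {
  singles <- expand.grid(name = as.character(1:8), rate = c(10, 15),
                         stringsAsFactors = FALSE)
  singles$kind <- "single"
  chains <- expand.grid(
    name = c("1-3P-6D", "1-4P-7D", "1-5P-8D",
             "1-6D-3P", "1-7D-4P", "1-8D-6P"),
    rate = c(10, 15), stringsAsFactors = FALSE)
  chains$kind <- "multi"
  out <- rbind(singles, chains)
  out[, c("kind", "name", "rate")]
}

#' Configure the open-boundary unit-step validation limit
#'
#' Reduces the engine to a plain open-boundary exclusion process: a single
#' species with unit steps, no lateral movement, no processivity limit, no
#' reservoir kinetics (blocked motors stall rather than detach), entry at
#' rate `alpha` per lane per iteration and stochastic exit with
#' probability `beta`.  In the low-density phase the bulk density must
#' equal `alpha`, which is the closed-form oracle the mean-field
#' integrator also reproduces.
#'
#' @param alpha Entry rate per lane per iteration (< 1/2 for the
#'   low-density phase).
#' @param beta Exit probability per iteration.
#' @param n_sites Lattice length (default 200).
#' @param n_lanes Number of independent lanes run in parallel (default 2).
#' @param horizon_iters Total iterations.
#' @param burn_in_iters Iterations excluded from the density average.
#' @param seed Optional seed.
#' @return The `mmls_run`, with the measured bulk density (mean occupancy
#'   over the central half of the lattice, all lanes) in attribute
#'   `"bulk_density"`.
#' @export
tasep_limit_run <- function(alpha = 0.2, beta = 0.8, n_sites = 200,
                            n_lanes = 2, horizon_iters = 200000,
                            burn_in_iters = 20000, seed = NULL) {
  geo <- lattice_geometry(n_lanes = n_lanes, mt_length_nm = n_sites * 8,
                          site_spacing_nm = 8, dt_s = 1)
  sc <- scenario_spec(geometry = geo, lateral_allowed = FALSE)
  big <- .Machine$integer.max %/% 4L
  sp <- list(
    fast = species_params("tracer", velocity_nm_s = 8, processivity_nm = 8,
                          lifetime_s = Inf, geometry = geo,
                          velocity_steps = 1L, processivity_sites = big),
    slow = species_params("unused", velocity_nm_s = 8, processivity_nm = 8,
                          lifetime_s = Inf, geometry = geo,
                          velocity_steps = 1L, processivity_sites = big))
  run <- run_multi(sc,
                   influx = influx_config(rate_a = alpha * n_lanes,
                                          rate_b = 0),
                   species = sp, horizon_s = horizon_iters, seed = seed,
                   crowding_detach = FALSE, exit_prob = beta,
                   snapshot_every = 0, burn_in_s = burn_in_iters)
  dens <- run$sections[[1]]$density
  mid <- seq(round(n_sites * 0.25), round(n_sites * 0.75))
  attr(run, "bulk_density") <- mean(dens[, mid, 1])
  run
}
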