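#' Write a scenario specification to a YAML config file
#'
#' Serialises geometry, behavioural switches and either the canonical
#' scenario id or the explicit accessibility mask (as per-lane blocked-site
#' runs) so that a spec round-trips exactly.
#'
#' @param scenario A `scenario_spec`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_scenario_config <- function(scenario, path) {
  g <- scenario$geometry
  cfg <- list(
    n_lanes = g$n_lanes, n_sites = g$n_sites, mt_length_nm = g$mt_length_nm,
    site_spacing_nm = g$site_spacing_nm, dt_s = g$dt_s,
    scenario_id = if (is.na(scenario$scenario_id)) NULL
                  else scenario$scenario_id,
    lateral_allowed = scenario$lateral_allowed,
    stagger_fraction = scenario$stagger_fraction,
    stagger_end = scenario$stagger_end,
    channel_lane = scenario$channel_lane,
    reservoir_capacity = scenario$reservoir_capacity,
    atp_wait_s = scenario$atp_wait_s,
    blocked_sites = apply(!scenario$accessible, 1, which, simplify = FALSE),
    atp_zone_sites = apply(scenario$atp_wait > 0, 1, which, simplify = FALSE))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a scenario specification from a YAML config file
#'
#' @param path File written by [write_scenario_config()] (or hand-written
#'   with the same keys; `scenario_id` alone suffices for canonical
#'   scenarios).
#' @return A `scenario_spec`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geo <- lattice_geometry(n_lanes = cfg$n_lanes,
                          mt_length_nm = cfg$mt_length_nm,
                          site_spacing_nm = cfg$site_spacing_nm,
                          dt_s = cfg$dt_s)
  acc <- matrix(TRUE, geo$n_lanes, geo$n_sites)
  if (!is.null(cfg$blocked_sites))
    for (l in seq_along(cfg$blocked_sites)) {
      idx <- unlist(cfg$blocked_sites[[l]])
      if (length(idx)) acc[l, idx] <- FALSE
    }
  else if (!is.null(cfg$scenario_id))
    acc <- build_scenario(cfg$scenario_id, geo)$accessible
  spec <- scenario_spec(
    geometry = geo, accessible = acc,
    lateral_allowed = isTRUE(cfg$lateral_allowed),
    stagger_fraction = cfg$stagger_fraction %||% 0,
    stagger_end = cfg$stagger_end %||% "none",
    channel_lane = cfg$channel_lane,
    reservoir_capacity = cfg$reservoir_capacity %||% 50,
    atp_wait_s = cfg$atp_wait_s %||% 10,
    scenario_id = cfg$scenario_id %||% NA_integer_)
  if (!is.null(cfg$atp_zone_sites)) {
    wt <- seconds_to_iterations(spec$atp_wait_s, geo$dt_s)
    for (l in seq_along(cfg$atp_zone_sites)) {
      idx <- unlist(cfg$atp_zone_sites[[l]])
      if (length(idx)) spec$atp_wait[l, idx] <- wt
    }
  }
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
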