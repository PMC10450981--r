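#' Motility parameters for one kinesin species
#'
#' Holds a motor's speed, processivity (maximum run length before obligatory
#' detachment) and reservoir lifetime, in both physical and lattice units.
#' Lattice values default to half-up-rounded conversions of the physical
#' values but can be overridden where a canonical lattice value exists.
#'
#' @param name Species label, e.g. `"Kin3F"` or `"Kin1S"`.
#' @param velocity_nm_s Speed in nm/s.
#' @param processivity_nm Run length in nm.
#' @param lifetime_s Productive-reservoir lifetime in seconds; `Inf` makes
#'   leakage impossible (all detached motors eventually return).
#' @param geometry A [lattice_geometry()] supplying `dt_s` and spacing.
#' @param velocity_steps,processivity_sites,lifetime_iters Optional explicit
#'   lattice-unit overrides.
#' @return An object of class `species_params`.
#' @examples
#' species_params("Kin3F", 1350, 6240, 60)
#' @export
species_params <- function(name, velocity_nm_s, processivity_nm, lifetime_s,
                           geometry = lattice_geometry(),
                           velocity_steps = NULL, processivity_sites = NULL,
                           lifetime_iters = NULL) {
  dt <- geometry$dt_s
  l <- geometry$site_spacing_nm
  vs <- if (is.null(velocity_steps))
    velocity_to_steps(velocity_nm_s, dt, l) else as.integer(velocity_steps)
  ps <- if (is.null(processivity_sites))
    nm_to_sites(processivity_nm, l) else as.integer(processivity_sites)
  li <- if (is.null(lifetime_iters)) {
    if (is.infinite(lifetime_s)) .Machine$integer.max
    else seconds_to_iterations(lifetime_s, dt)
  } else as.integer(lifetime_iters)
  if (vs < 1 || ps < 1 || li < 1)
    stop("velocity_steps, processivity_sites and lifetime_iters must be >= 1")
  structure(
    list(name = name, velocity_nm_s = velocity_nm_s, velocity_steps = vs,
         processivity_nm = processivity_nm, processivity_sites = ps,
         lifetime_s = lifetime_s, lifetime_iters = li),
    class = "species_params")
}

#' Default dual-kinesin species table
#'
#' The fast species is a kinesin-3 (KIF1A-like: 1350 nm/s, 6240 nm
#' processivity = 780 sites) and the slow species a conventional kinesin-1
#' (KHC-like: 620 nm/s, 1070 nm processivity, taken as 130 sites on the
#' lattice).  Both share a 60 s reservoir lifetime.
#'
#' @param geometry A [lattice_geometry()].
#' @param lifetime_s Reservoir lifetime in seconds for both species
#'   (default 60; use `Inf` for non-limiting lifetimes).
#' @return A list with elements `fast` and `slow`, each a `species_params`.
#' @export
default_species <- function(geometry = lattice_geometry(), lifetime_s = 60) {
  list(
    fast = species_params("Kin3F", 1350, 6240, lifetime_s, geometry),
    slow = species_params("Kin1S", 620, 1070, lifetime_s, geometry,
                          processivity_sites = 130L))
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf(
    "<species_params> %s: v = %g nm/s (%d steps/iter), p = %g nm (%d sites), lifetime = %g s (%d iters)\n",
    x$name, x$velocity_nm_s, x$velocity_steps, x$processivity_nm,
    x$processivity_sites, x$lifetime_s, x$lifetime_iters))
  invisible(x)
}

species_table <- function(species) {
  stopifnot(is.list(species), !is.null(species$fast), !is.null(species$slow))
  rbind(
    c(species$fast$velocity_steps, species$fast$processivity_sites,
      species$fast$lifetime_iters),
    c(species$slow$velocity_steps, species$slow$processivity_sites,
      species$slow$lifetime_iters))
}
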