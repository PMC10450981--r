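# Unit conversions between physical (nm, s) and lattice (sites, iterations)
# quantities.  All conversions round half-up so that e.g. 12.5% of 500 sites
# gives 63 blocked sites, and are exact for the default parameter table.

round_half_up <- function(x) floor(x + 0.5)

#' Convert a physical length to a site count
#'
#' @param length_nm Length in nanometres.
#' @param spacing_nm Lattice spacing in nanometres (one kinesin binding site,
#'   default 8 nm, the step size of dimeric kinesin).
#' @return Integer number of binding sites, rounded half-up.
#' @examples
#' nm_to_sites(4000, 8)  # 500 sites on a 4 um microtubule
#' @export
nm_to_sites <- function(length_nm, spacing_nm = 8) {
  if (any(length_nm <= 0) || any(spacing_nm <= 0))
    stop("length_nm and spacing_nm must be positive")
  as.integer(round_half_up(length_nm / spacing_nm))
}

#' Convert a duration to an iteration count
#'
#' @param duration_s Duration in seconds (may be 0).
#' @param dt_s Duration of one iteration in seconds (default 0.04).
#' @return Integer iteration count, rounded half-up.
#' @examples
#' seconds_to_iterations(600, 0.04)  # 15000 iterations
#' @export
seconds_to_iterations <- function(duration_s, dt_s = 0.04) {
  if (any(duration_s < 0)) stop("duration_s must be non-negative")
  if (any(dt_s <= 0)) stop("dt_s must be positive")
  as.integer(round_half_up(duration_s / dt_s))
}

#' Convert a motor speed to lattice steps per iteration
#'
#' Any positive speed is clamped to a minimum of one step per iteration so
#' that every motor can make progress under the hopping rules.
#'
#' @param velocity_nm_s Speed in nm/s.
#' @param dt_s Iteration duration in seconds.
#' @param spacing_nm Site spacing in nm.
#' @return Integer steps per iteration (>= 1).
#' @examples
#' velocity_to_steps(1350, 0.04, 8)  # 7 steps: fast kinesin-3
#' velocity_to_steps(620, 0.04, 8)   # 3 steps: slow kinesin-1
#' @export
velocity_to_steps <- function(velocity_nm_s, dt_s = 0.04, spacing_nm = 8) {
  if (any(velocity_nm_s <= 0) || any(dt_s <= 0) || any(spacing_nm <= 0))
    stop("all arguments must be positive")
  as.integer(pmax(1L, round_half_up(velocity_nm_s * dt_s / spacing_nm)))
}
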