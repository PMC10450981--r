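#' Lattice geometry of one microtubule bundle segment
#'
#' Describes a bundle of parallel microtubules (lanes) as a 2-D lattice of
#' kinesin binding sites.  One site corresponds to an 8 nm dimeric kinesin
#' step; one iteration corresponds to 40 ms of real time by default.
#'
#' @param n_lanes Number of parallel microtubules (>= 2; default 3).
#' @param mt_length_nm Length of each microtubule in nm (default 4000).
#' @param site_spacing_nm Binding-site spacing in nm (default 8).
#' @param dt_s Iteration duration in seconds (default 0.04).
#' @return An object of class `lattice_geometry` with fields `n_lanes`,
#'   `n_sites`, `mt_length_nm`, `site_spacing_nm`, `dt_s`.
#' @examples
#' geo <- lattice_geometry()
#' geo$n_sites  # 500
#' @export
lattice_geometry <- function(n_lanes = 3, mt_length_nm = 4000,
                             site_spacing_nm = 8, dt_s = 0.04) {
  n_lanes <- as.integer(n_lanes)
  if (n_lanes < 2) stop("n_lanes must be >= 2")
  n_sites <- nm_to_sites(mt_length_nm, site_spacing_nm)
  if (n_sites < 3) stop("lattice must have at least 3 sites")
  structure(
    list(n_lanes = n_lanes, n_sites = n_sites, mt_length_nm = mt_length_nm,
         site_spacing_nm = site_spacing_nm, dt_s = dt_s),
    class = "lattice_geometry")
}

#' @export
print.lattice_geometry <- function(x, ...) {
  cat(sprintf("<lattice_geometry> %d lanes x %d sites (%g nm, %g nm/site, dt = %g s)\n",
              x$n_lanes, x$n_sites, x$mt_length_nm, x$site_spacing_nm, x$dt_s))
  invisible(x)
}
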