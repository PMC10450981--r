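#' Mean-field parameters for the reduced exclusion-process limits
#'
#' Parameters of the master-equation description of unit-step transport
#' with Langmuir kinetics used as an independent validation oracle for the
#' stochastic engine: entry rate `alpha`, exit rate `beta`, bulk
#' attachment/detachment rates `omega_a`/`omega_d`, and (two-lane case) a
#' lane-change rate `omega_l`.  `v` is the slow-species speed ratio used
#' only by the two-species coupling terms ([two_species_rhs()]).
#'
#' @param n_sites Lattice length.
#' @param alpha,beta Entry and exit rates.
#' @param omega_a,omega_d Attachment and detachment rates.
#' @param omega_l Lane-change rate (two-lane case).
#' @param v Slow-species speed ratio in (0, 1].
#' @return An object of class `meanfield_params`.
#' @export
meanfield_params <- function(n_sites = 200, alpha = 0.2, beta = 0.8,
                             omega_a = 0, omega_d = 0, omega_l = 0, v = 1) {
  if (any(c(alpha, beta, omega_a, omega_d, omega_l) < 0))
    stop("rates must be >= 0")
  if (v <= 0 || v > 1) stop("v must be in (0, 1]")
  structure(list(n_sites = as.integer(n_sites), alpha = alpha, beta = beta,
                 omega_a = omega_a, omega_d = omega_d, omega_l = omega_l,
                 v = v),
            class = "meanfield_params")
}

single_lane_rhs <- function(rho, p) {
  N <- length(rho)
  d <- numeric(N)
  # bulk: gain from the left hop, loss to the right hop, Langmuir kinetics
  if (N > 2) {
    i <- 2:(N - 1)
    d[i] <- rho[i - 1] * (1 - rho[i]) - rho[i] * (1 - rho[i + 1]) +
      p$omega_a * (1 - rho[i]) - p$omega_d * rho[i]
  }
  d[1] <- p$alpha * (1 - rho[1]) - rho[1] * (1 - rho[2])
  d[N] <- rho[N - 1] * (1 - rho[N]) - p$beta * rho[N]
  d
}

mf_step_size <- function(p) {
  0.1 / (1 + max(p$alpha, p$beta, p$omega_a, p$omega_d, p$omega_l, 1))
}

#' Steady-state density profile of the single-lane mean-field equations
#'
#' Forward-Euler integration of the factorised master equation (bulk
#' hopping with attachment/detachment, open boundaries) to steady state.
#' The step size is chosen so that densities provably stay in `[0, 1]`; a
#' density leaving that interval is treated as an error, not clipped.
#'
#' @param params A [meanfield_params()].
#' @param tol Convergence tolerance on `max |d rho / dt|` (default 1e-9).
#' @param max_steps Maximum Euler steps before signalling non-convergence.
#' @return Numeric vector `rho` of per-site steady-state densities with
#'   attributes `residual` and `steps`.
#' @examples
#' rho <- integrate_single_lane(meanfield_params(n_sites = 50))
#' mean(rho[20:30])  # low-density phase: bulk density = alpha
#' @export
integrate_single_lane <- function(params, tol = 1e-9, max_steps = 500000) {
  p <- params
  rho <- rep(0.5, p$n_sites)  # uninformative start, away from any boundary
  h <- mf_step_size(p)
  for (s in seq_len(max_steps)) {
    d <- single_lane_rhs(rho, p)
    rho <- rho + h * d
    if (any(rho < 0) || any(rho > 1))
      stop("density left [0, 1]; step size too large")
    if (max(abs(d)) < tol)
      return(structure(rho, residual = max(abs(d)), steps = s))
  }
  stop(sprintf("no steady state within %d steps (residual %.3g)",
               max_steps, max(abs(single_lane_rhs(rho, p)))))
}

two_lane_rhs <- function(r1, r2, p, printed_form = FALSE) {
  N <- length(r1)
  d1 <- single_lane_rhs(r1, p)
  d2 <- single_lane_rhs(r2, p)
  if (p$omega_l > 0 && N > 2) {
    i <- 2:(N - 1)
    # loss in a lane when a motor and its follower queue up and the other
    # lane's site is free; symmetric gain in the other lane
    loss1 <- p$omega_l * r1[i] * r1[i + 1] * (1 - r2[i])
    loss2 <- p$omega_l * r2[i] * r2[i + 1] * (1 - r1[i])
    if (printed_form) {
      # the asymmetric form as printed: both lanes lose the lane-1 term
      d1[i] <- d1[i] - loss1
      d2[i] <- d2[i] - loss1
    } else {
      d1[i] <- d1[i] - loss1 + loss2
      d2[i] <- d2[i] - loss2 + loss1
    }
  }
  list(d1 = d1, d2 = d2)
}

#' Steady-state density profiles of the coupled two-lane equations
#'
#' As [integrate_single_lane()] but for two lanes coupled by a
#' lane-change term.  The printed version of the coupled equations uses
#' the same lane-change loss term in both lanes (an apparent typo); by
#' default the symmetric counterpart is used, with `printed_form = TRUE`
#' reproducing the printed form.
#'
#' @inheritParams integrate_single_lane
#' @param printed_form Use the asymmetric printed coupling term.
#' @return List with components `lane1` and `lane2` (density vectors) and
#'   attributes `residual` and `steps`.
#' @export
integrate_two_lane <- function(params, tol = 1e-9, max_steps = 500000,
                               printed_form = FALSE) {
  p <- params
  r1 <- rep(0.5, p$n_sites)
  r2 <- r1
  h <- mf_step_size(p)
  for (s in seq_len(max_steps)) {
    d <- two_lane_rhs(r1, r2, p, printed_form)
    r1 <- r1 + h * d$d1
    r2 <- r2 + h * d$d2
    if (any(c(r1, r2) < 0) || any(c(r1, r2) > 1))
      stop("density left [0, 1]; step size too large")
    res <- max(abs(c(d$d1, d$d2)))
    if (res < tol)
      return(structure(list(lane1 = r1, lane2 = r2),
                       residual = res, steps = s))
  }
  stop(sprintf("no steady state within %d steps", max_steps))
}

#' Gain/loss decomposition of the two-species coupled density equations
#'
#' Evaluates the right-hand side of the two-species (fast `n`, slow `m`)
#' asymmetric-coupling density equations for one lane flanked by two
#' neighbour lanes, split into named gain and loss terms.  These equations
#' are analytically and numerically intractable in full (the stochastic
#' engine is the solution method); this evaluation exists to document the
#' structure and to check algebraic consistency: every lane-change loss in
#' a lane reappears as a gain in a neighbour lane.
#'
#' @param n,m Density vectors of the fast and slow species on the focal
#'   lane.
#' @param n_up,m_up,n_down,m_down Densities on the two neighbour lanes.
#' @param params A [meanfield_params()] supplying `omega_a` (reattachment),
#'   `omega_d` (detachment), `omega_l` (lane change) and `v`.
#' @return List with per-site vectors `dn`, `dm` and the named lateral
#'   `loss`/`gain` components for each species.
#' @export
two_species_rhs <- function(n, m, n_up, m_up, n_down, m_down, params) {
  p <- params
  N <- length(n)
  i <- 2:(N - 1)
  free <- function(nn, mm) 1 - nn - mm
  dn <- numeric(N); dm <- numeric(N)
  # transport + Langmuir kinetics on the focal lane
  dn[i] <- p$omega_a * (1 - n[i - 1] * n[i] * n[i + 1] -
                          m[i - 1] * m[i] * m[i + 1]) - p$omega_d * n[i] +
    n[i - 1] * free(n[i], m[i]) - n[i] * free(n[i + 1], m[i + 1])
  dm[i] <- p$omega_a * (1 - n[i - 1] * n[i] * n[i + 1] -
                          m[i - 1] * m[i] * m[i + 1]) - p$omega_d * m[i] +
    p$v * m[i - 1] * free(n[i], m[i]) - p$v * m[i] * free(n[i + 1], m[i + 1])
  # lateral exchange: queueing pairs leave for a free neighbour-lane site
  loss_n <- loss_m <- gain_n <- gain_m <- numeric(N)
  loss_n[i] <- p$omega_l * n[i] * n[i + 1] *
    free(n_up[i], m_up[i]) * free(n_down[i], m_down[i])
  loss_m[i] <- p$omega_l * m[i] * m[i + 1] *
    free(n_up[i], m_up[i]) * free(n_down[i], m_down[i])
  gain_n[i] <- p$omega_l * (n_up[i] * n_up[i + 1] * free(n[i], m[i]) +
                              n_down[i] * n_down[i + 1] * free(n[i], m[i]))
  gain_m[i] <- p$omega_l * (m_up[i] * m_up[i + 1] * free(n[i], m[i]) +
                              m_down[i] * m_down[i + 1] * free(n[i], m[i]))
  list(dn = dn - loss_n + gain_n, dm = dm - loss_m + gain_m,
       loss_n = loss_n, gain_n = gain_n, loss_m = loss_m, gain_m = gain_m)
}
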