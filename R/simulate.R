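# Integration backend: stiff solver (lsoda) over the compiled C
# right-hand side. The inhibitor forcing within one call is
# u(t) = u_target + (u0 - u_target) * exp(-k_wash (t - t0));
# k_wash = 0 clamps u at u0.

.parms_vector <- function(network, u_target = NULL, u0 = NULL,
                          k_wash = 0, t0 = 0) {
  u <- network$u
  if (is.null(u_target)) u_target <- u
  if (is.null(u0)) u0 <- u
  c(as.numeric(network$kinetics), u_target, u0, k_wash, t0)
}

.ode <- function(y, times, network, parms = NULL, rtol = 1e-8, atol = 1e-8) {
  if (is.null(parms)) parms <- .parms_vector(network)
  out <- deSolve::ode(
    y = y, times = times, parms = parms,
    func = "rhoswitch_derivs", initfunc = "rhoswitch_initmod",
    dllname = "rhoswitch", nout = 1, outnames = "u",
    method = "lsoda", rtol = rtol, atol = atol, maxsteps = 200000
  )
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed (istate = ", attr(out, "istate")[1],
         ") at t = ", max(out[, "time"]), " min")
  }
  out
}

#' Simulate a trajectory of the network
#'
#' Integrates the model ODE with a stiff-capable solver from a given
#' initial state. Conservation of all six moiety totals along the output is
#' verified to relative tolerance 1e-6.
#'
#' @param network an `rr_network` (its `u` is clamped for the whole run).
#' @param state0 initial state vector (named over [species_names()]),
#'   consistent with the network's moiety totals.
#' @param t_end end time (min).
#' @param dt output time step (min); the solver chooses its own internal
#'   steps.
#' @param tol relative/absolute integration tolerance.
#' @return Matrix with a `time` column and one column per species
#'   (class `rr_trajectory`).
#' @export
#' @examples
#' nw <- build_network(default_abundances(), default_kinetics(), u = 0)
#' tr <- simulate_network(nw, state_inactive(nw), t_end = 60, dt = 5)
#' tail(tr[, c("time", "RhoA_GTP", "Rac1_GTP")], 3)
simulate_network <- function(network, state0, t_end, dt = t_end / 100,
                             tol = 1e-8) {
  y0 <- validate_state(state0)
  .check_totals(y0, network)
  times <- unique(c(seq(0, t_end, by = dt), t_end))
  out <- .ode(y0, times, network, rtol = tol, atol = tol)
  traj <- out[, c("time", species_names()), drop = FALSE]
  .check_conservation(traj, network)
  class(traj) <- c("rr_trajectory", class(traj))
  traj
}

.check_totals <- function(state, network, rtol = 1e-6) {
  tot <- moiety_totals(state)
  ref <- as.numeric(network$abundances)[match(names(tot), abundance_names())]
  scale <- pmax(abs(ref), 1)
  if (any(abs(tot - ref) / scale > rtol)) {
    bad <- names(tot)[abs(tot - ref) / scale > rtol]
    stop("initial state inconsistent with moiety totals: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

.check_conservation <- function(traj, network, rtol = 1e-6) {
  ref <- moiety_totals(traj[1, species_names()])
  last <- moiety_totals(traj[nrow(traj), species_names()])
  scale <- pmax(abs(ref), 1)
  if (any(abs(last - ref) / scale > rtol)) {
    stop("moiety conservation violated along trajectory")
  }
  invisible(TRUE)
}

# Integrate until quiescence: ||rhs||_inf below `rate_tol` (nM/min), or
# relative state change below `drift_tol` over a 100 min window. Returns
# list(state, converged, t).
.relax <- function(network, state0, t_max = 1e5, rate_tol = 1e-8,
                   drift_tol = 1e-9, chunk = 200) {
  y <- validate_state(state0)
  t <- 0
  scale <- max(sum(as.numeric(network$abundances)), 1)
  while (t < t_max) {
    span <- min(chunk, t_max - t)
    out <- try(.ode(y, c(0, span), network), silent = TRUE)
    if (inherits(out, "try-error")) {
      return(list(state = y, converged = FALSE, t = t))
    }
    y_new <- pmax(out[nrow(out), species_names()], 0)
    if (any(!is.finite(y_new))) {
      return(list(state = y, converged = FALSE, t = t))
    }
    dy <- rhs(y_new, network)
    drift <- max(abs(y_new - y)) / scale * (100 / span)
    y <- y_new
    t <- t + span
    if ((all(is.finite(dy)) && max(abs(dy)) < rate_tol) ||
        drift < drift_tol) {
      return(list(state = y, converged = TRUE, t = t))
    }
    chunk <- min(chunk * 2, 2e4)
  }
  list(state = y, converged = FALSE, t = t)
}
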