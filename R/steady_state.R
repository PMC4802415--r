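# Steady-state machinery: the six conservation laws eliminate six species,
# leaving a reduced 8-variable root-finding problem.

.free_vars <- c("Rac1_GTP", "RhoA_GTP", "cPAK", "pPAK", "iPAK_I",
                "pGEFH1", "pGEFH1_1433", "GAPa")
.elim_vars <- c("Rac1_GDP", "RhoA_GDP", "iPAK", "GEFH1", "F1433", "GAPi")

# reconstruct the full state from the reduced coordinates (no clamping:
# smoothness matters for finite-difference Jacobians)
.full_state <- function(z, network) {
  ab <- network$abundances
  x <- setNames(numeric(14), species_names())
  x[.free_vars] <- z
  x["Rac1_GDP"] <- ab[["rac1_tot"]] - z[1] - z[3]
  x["RhoA_GDP"] <- ab[["rhoa_tot"]] - z[2]
  x["iPAK"]     <- ab[["pak_tot"]] - z[3] - z[4] - z[5]
  x["GEFH1"]    <- ab[["gefh1_tot"]] - z[6] - z[7]
  x["F1433"]    <- ab[["s1433_tot"]] - z[7]
  x["GAPi"]     <- ab[["racgap_tot"]] - z[8]
  x
}

# rhs without state validation (reduced coordinates may step slightly
# outside the feasible region during root finding / differencing)
.rhs_raw <- function(x, network) {
  k <- network$kinetics
  u <- network$u
  v <- c(
    k[["Vb_racgef"]] * x[["Rac1_GDP"]] / (k[["Km_r1"]] + x[["Rac1_GDP"]]),
    (k[["kcat_gap"]] * x[["GAPa"]] + k[["Vb_racgap"]]) * x[["Rac1_GTP"]] /
      (k[["Km_r2"]] + x[["Rac1_GTP"]]),
    (k[["kcat_gef"]] * x[["GEFH1"]] + k[["Vb_rhogef"]]) * x[["RhoA_GDP"]] /
      (k[["Km_r3"]] + x[["RhoA_GDP"]]),
    k[["Vb_rhogap"]] * x[["RhoA_GTP"]] / (k[["Km_r4"]] + x[["RhoA_GTP"]]),
    k[["kon_pak"]] * x[["Rac1_GTP"]] * x[["iPAK"]] - k[["koff_pak"]] * x[["cPAK"]],
    k[["k_auto"]] * x[["cPAK"]],
    k[["V_ppase"]] * x[["pPAK"]] / (k[["Km_p"]] + x[["pPAK"]]),
    k[["kcat_pakgef"]] * x[["pPAK"]] * x[["GEFH1"]] / (k[["Km_g"]] + x[["GEFH1"]]),
    k[["V_gppase"]] * x[["pGEFH1"]] / (k[["Km_gp"]] + x[["pGEFH1"]]),
    k[["kon_14"]] * x[["pGEFH1"]] * x[["F1433"]] - k[["koff_14"]] * x[["pGEFH1_1433"]],
    k[["kcat_rho"]] * x[["RhoA_GTP"]] * x[["GAPi"]] / (k[["Km_ga"]] + x[["GAPi"]]),
    k[["V_gapoff"]] * x[["GAPa"]] / (k[["Km_gd"]] + x[["GAPa"]]),
    k[["kon_i"]] * u * x[["iPAK"]],
    k[["koff_i"]] * x[["iPAK_I"]]
  )
  dx <- as.numeric(network$stoichiometry %*% v)
  names(dx) <- species_names()
  dx
}

.reduced_residual <- function(z, network) {
  .rhs_raw(.full_state(z, network), network)[.free_vars]
}

.free_caps <- function(network) {
  ab <- network$abundances
  c(ab[["rac1_tot"]], ab[["rhoa_tot"]],
    min(ab[["rac1_tot"]], ab[["pak_tot"]]), ab[["pak_tot"]], ab[["pak_tot"]],
    ab[["gefh1_tot"]], min(ab[["gefh1_tot"]], ab[["s1433_tot"]]),
    ab[["racgap_tot"]])
}

# Newton-type polish of a near-steady state: damped Levenberg-Marquardt
# on the reduced residual, implemented directly (it is called from inside
# other optimizers, so it must not share optimizer state). Returns the
# polished full state or NULL.
.polish <- function(state, network, tol = 1e-8, max_iter = 100) {
  caps <- .free_caps(network)
  z <- pmin(pmax(state[.free_vars], 0), caps)
  f <- .reduced_residual(z, network)
  if (any(!is.finite(f))) return(NULL)
  lambda <- 1e-3
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol * 1e-2) break
    J <- matrix(0, 8, 8)
    for (j in 1:8) {
      h <- 1e-7 * max(abs(z[j]), 1)
      zp <- z; zp[j] <- z[j] + h
      zm <- z; zm[j] <- max(z[j] - h, 0)
      J[, j] <- (.reduced_residual(zp, network) -
                 .reduced_residual(zm, network)) / (zp[j] - zm[j])
    }
    H <- crossprod(J)
    g <- crossprod(J, f)
    improved <- FALSE
    for (tries in 1:12) {
      step <- try(solve(H + lambda * diag(pmax(diag(H), 1e-12)), -g),
                  silent = TRUE)
      if (!inherits(step, "try-error")) {
        z_new <- pmin(pmax(z + as.numeric(step), 0), caps)
        f_new <- .reduced_residual(z_new, network)
        if (all(is.finite(f_new)) && sum(f_new^2) < sum(f^2)) {
          z <- z_new; f <- f_new
          lambda <- max(lambda / 3, 1e-12)
          improved <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) break
  }
  x <- .full_state(z, network)
  if (any(x < -1e-9)) return(NULL)
  if (max(abs(.rhs_raw(x, network))) > tol) return(NULL)
  pmax(x, 0)
}

# bisection on basin membership along the segment between two stable
# states; polish from the boundary point
.find_saddle <- function(network, sA, sB, scale, ss_tol, max_bisect = 40) {
  attractor <- function(x) {
    y <- .relax(network, pmax(x, 0), t_max = 5e3, rate_tol = ss_tol)$state
    dA <- sqrt(sum((y - sA)^2)); dB <- sqrt(sum((y - sB)^2))
    dA < dB
  }
  a <- 0; b <- 1
  for (it in seq_len(max_bisect)) {
    m <- (a + b) / 2
    x <- sA * (1 - m) + sB * m
    if (attractor(x)) a <- m else b <- m
    if ((b - a) * sqrt(sum((sA - sB)^2)) / scale < 1e-7) break
  }
  m <- (a + b) / 2
  pol <- .polish(sA * (1 - m) + sB * m, network, tol = ss_tol)
  # reject if it polished back onto one of the stable states
  if (!is.null(pol) &&
      (sqrt(sum((pol - sA)^2)) / scale < 1e-6 ||
       sqrt(sum((pol - sB)^2)) / scale < 1e-6)) {
    return(NULL)
  }
  pol
}

#' Jacobian of the reduced system at a state
#'
#' Central finite differences (relative step 1e-6) of the
#' conservation-reduced 8-variable system.
#'
#' @param network an `rr_network`.
#' @param state full 14-species state vector.
#' @return 8 x 8 Jacobian matrix (1/min).
#' @export
reduced_jacobian <- function(network, state) {
  z <- validate_state(state)[.free_vars]
  n <- length(z)
  J <- matrix(0, n, n, dimnames = list(.free_vars, .free_vars))
  for (j in seq_len(n)) {
    h <- 1e-6 * max(abs(z[j]), 1)
    zp <- z; zp[j] <- z[j] + h
    zm <- z; zm[j] <- z[j] - h
    J[, j] <- (.reduced_residual(zp, network) -
               .reduced_residual(zm, network)) / (2 * h)
  }
  J
}

#' Classify the stability of a steady state
#'
#' Computes the Jacobian of the conservation-reduced system by central
#' finite differences and classifies the state by the largest real part of
#' its eigenvalues: stable if below `-eps`, unstable if above `+eps`,
#' marginal otherwise.
#'
#' @param network an `rr_network`.
#' @param state steady state (full 14-species vector); it is an error if
#'   `max(abs(rhs(state)))` exceeds `ss_tol`.
#' @param eps stability margin on the leading eigenvalue (1/min).
#' @param ss_tol residual tolerance of the steady-state precondition
#'   (nM/min).
#' @return List with `stability` (one of `"stable"`, `"unstable"`,
#'   `"marginal"`) and `leading_eigenvalue` (largest real part, 1/min).
#' @export
classify_stability <- function(network, state, eps = 1e-6, ss_tol = 1e-6) {
  res <- max(abs(.rhs_raw(validate_state(state), network)))
  if (res > ss_tol) {
    stop("state is not steady: max |rhs| = ", signif(res, 3),
         " nM/min exceeds ", ss_tol)
  }
  J <- reduced_jacobian(network, state)
  lam <- max(Re(eigen(J, only.values = TRUE)$values))
  stability <- if (lam < -eps) "stable" else if (lam > eps) "unstable" else "marginal"
  list(stability = stability, leading_eigenvalue = lam)
}

.lhs_starts <- function(network, n, seed) {
  ab <- network$abundances
  set.seed(seed)
  L <- lhs::randomLHS(n, 8)
  starts <- vector("list", n)
  for (i in seq_len(n)) {
    l <- L[i, ]
    rac_gtp <- l[1] * ab[["rac1_tot"]]
    cpak <- l[2] * min(ab[["rac1_tot"]] - rac_gtp, ab[["pak_tot"]])
    ppak <- l[3] * (ab[["pak_tot"]] - cpak)
    ipak_i <- l[4] * (ab[["pak_tot"]] - cpak - ppak)
    rho_gtp <- l[5] * ab[["rhoa_tot"]]
    seq14 <- l[6] * min(ab[["gefh1_tot"]], ab[["s1433_tot"]])
    pgef <- l[7] * (ab[["gefh1_tot"]] - seq14)
    gapa <- l[8] * ab[["racgap_tot"]]
    z <- c(rac_gtp, rho_gtp, cpak, ppak, ipak_i, pgef, seq14, gapa)
    starts[[i]] <- pmax(.full_state(z, network), 0)
  }
  starts
}

.dedup_states <- function(states, scale, rtol = 1e-6) {
  kept <- list()
  for (s in states) {
    new <- TRUE
    for (k in kept) {
      if (sqrt(sum((s - k)^2)) / scale < rtol) { new <- FALSE; break }
    }
    if (new) kept <- c(kept, list(s))
  }
  kept
}

#' Find all steady states of a network
#'
#' Multi-start search: Latin-hypercube initial states on the
#' moiety-feasible region plus deterministic corner states (all-inactive,
#' all-active, and the two mixed corners targeting the high-Rac/low-Rho and
#' low-Rac/high-Rho activity patterns). Each start is integrated to
#' quiescence and polished by root finding on the conservation-reduced
#' system; duplicates are merged at relative L2 distance below 1e-6.
#' Unstable saddle states are additionally sought by root finding from
#' midpoints between every pair of distinct stable states.
#'
#' @param network an `rr_network`.
#' @param n_starts number of Latin-hypercube starts (>= 1) in addition to
#'   the deterministic corners.
#' @param seed RNG seed for the Latin-hypercube design.
#' @param ss_tol steady-state tolerance on `max(abs(rhs))` (nM/min).
#' @param t_max maximum integration time per start (min); a start that has
#'   not become quiescent by then and does not polish to a root is recorded
#'   as non-convergent (bounded non-convergence is the oscillation screen
#'   used by [dynamics_class()]).
#' @return List of steady states (class `rr_steady_states`); each element
#'   has `state`, `residual` (nM/min), `stability` and
#'   `leading_eigenvalue`. The attribute `nonconvergent` counts starts that
#'   neither settled nor polished. Returns an empty list with a warning if
#'   no start converges.
#' @export
#' @examples
#' nw <- build_network(default_abundances(), default_kinetics(), u = 500)
#' ss <- find_steady_states(nw, n_starts = 10, seed = 1)
#' vapply(ss, function(s) s$stability, character(1))
find_steady_states <- function(network, n_starts = 50, seed = 1,
                               ss_tol = 1e-8, t_max = 1e5) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  starts <- c(
    list(state_inactive(network), state_active(network),
         state_low_rho(network), state_high_rho(network)),
    .lhs_starts(network, n_starts, seed)
  )
  scale <- max(sqrt(sum(as.numeric(network$abundances)^2)), 1)
  found <- list()
  nonconv <- 0L
  for (s0 in starts) {
    rl <- .relax(network, s0, t_max = t_max, rate_tol = ss_tol)
    pol <- .polish(rl$state, network, tol = ss_tol)
    if (is.null(pol)) {
      if (!rl$converged) nonconv <- nonconv + 1L
      next
    }
    found <- c(found, list(pol))
  }
  found <- .dedup_states(found, scale)
  states <- lapply(found, function(x) {
    cls <- classify_stability(network, x, ss_tol = max(ss_tol * 100, 1e-6))
    list(state = x, residual = max(abs(.rhs_raw(x, network))),
         stability = cls$stability,
         leading_eigenvalue = cls$leading_eigenvalue)
  })

  # saddle search between distinct stable states: bisect the straight line
  # between the two attractors on basin membership, then polish from the
  # basin boundary (the separatrix crossing lies near the saddle's stable
  # manifold)
  stable <- Filter(function(s) s$stability == "stable", states)
  if (length(stable) >= 2) {
    for (i in seq_len(length(stable) - 1)) {
      for (j in seq(i + 1, length(stable))) {
        pol <- .find_saddle(network, stable[[i]]$state, stable[[j]]$state,
                            scale, ss_tol)
        if (is.null(pol)) next
        dup <- any(vapply(states, function(s) {
          sqrt(sum((s$state - pol)^2)) / scale < 1e-6
        }, logical(1)))
        if (!dup) {
          cls <- classify_stability(network, pol,
                                    ss_tol = max(ss_tol * 100, 1e-6))
          states <- c(states, list(list(
            state = pol, residual = max(abs(.rhs_raw(pol, network))),
            stability = cls$stability,
            leading_eigenvalue = cls$leading_eigenvalue)))
        }
      }
    }
  }

  if (length(states) == 0) warning("no start converged to a steady state")
  structure(states, class = "rr_steady_states", nonconvergent = nonconv)
}

#' @export
print.rr_steady_states <- function(x, ...) {
  cat(length(x), "steady state(s)\n")
  for (s in x) {
    cat(sprintf("  %-8s  RhoA_GTP=%8.3f  Rac1_GTP=%8.3f  |rhs|=%.2e  Re(lam)=%+.3e\n",
                s$stability, s$state[["RhoA_GTP"]], s$state[["Rac1_GTP"]],
                s$residual, s$leading_eigenvalue))
  }
  invisible(x)
}

#' Dynamics class of a network
#'
#' Classifies the network as `bistable` (exactly two stable steady states),
#' `monostable` (exactly one), or `other` (zero or more than two stable
#' states, or a bounded non-convergent trajectory, the screen for sustained
#' oscillation).
#'
#' @inheritParams find_steady_states
#' @return Character scalar: `"monostable"`, `"bistable"` or `"other"`.
#' @export
dynamics_class <- function(network, n_starts = 12, seed = 1,
                           ss_tol = 1e-8, t_max = 2e4) {
  ss <- find_steady_states(network, n_starts = n_starts, seed = seed,
                           ss_tol = ss_tol, t_max = t_max)
  if (attr(ss, "nonconvergent") > 0) return("other")
  n_stable <- sum(vapply(ss, function(s) s$stability == "stable", logical(1)))
  if (n_stable == 2) "bistable" else if (n_stable == 1) "monostable" else "other"
}
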