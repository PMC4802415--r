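#' Build a reaction network
#'
#' Assembles abundances, kinetic constants and the clamped free-inhibitor
#' concentration into a validated network object carrying the stoichiometry
#' matrix and precomputed moiety masks. Moiety conservation is verified at
#' construction: every moiety-membership mask is orthogonal to every
#' stoichiometry column.
#'
#' @param abundances output of [abundances()] (or a named numeric vector
#'   with the same fields).
#' @param kinetics output of [kinetics()] (or a named numeric vector with
#'   all 27 constants).
#' @param u clamped free intracellular inhibitor concentration (nM). The
#'   inhibitor is an external forcing, not a conserved species: small
#'   molecules exchange across the membrane within minutes, so depletion of
#'   the free pool by PAK binding is neglected.
#' @return Object of class `rr_network`.
#' @export
#' @examples
#' nw <- build_network(default_abundances(), default_kinetics(), u = 0)
#' nw
build_network <- function(abundances, kinetics, u = 0) {
  ab <- as_abundances(abundances)
  kin <- as_kinetics(kinetics)
  if (!is.finite(u) || u < 0) stop("inhibitor level 'u' must be finite and >= 0")
  S <- .stoichiometry()
  masks <- moiety_masks()
  for (m in names(masks)) {
    resid <- as.numeric(masks[[m]] %*% S)
    if (any(abs(resid) > 0)) {
      stop("stoichiometry violates conservation of moiety ", m)
    }
  }
  structure(
    list(abundances = ab, kinetics = kin, u = u,
         stoichiometry = S, masks = masks),
    class = "rr_network"
  )
}

#' @export
print.rr_network <- function(x, ...) {
  cat("Rac1-RhoA-PAK reaction network\n")
  cat("  species:  ", length(species_names()), "\n")
  cat("  reactions:", length(reaction_names()), "\n")
  cat("  inhibitor u:", x$u, "nM\n")
  cat("  totals (nM):",
      paste(sprintf("%s=%g", names(x$abundances), as.numeric(x$abundances)),
            collapse = " "), "\n")
  invisible(x)
}

# 0/1 membership mask per moiety over the species order
moiety_masks <- function() {
  sp <- species_names()
  lapply(moiety_members(), function(members) {
    as.numeric(sp %in% members)
  })
}

validate_state <- function(state) {
  sp <- species_names()
  if (length(state) != length(sp)) {
    stop("state vector must have ", length(sp), " entries")
  }
  if (is.null(names(state))) names(state) <- sp
  state <- state[sp]
  if (any(!is.finite(state))) stop("state contains non-finite concentrations")
  if (any(state < -1e-9)) stop("state contains negative concentrations")
  pmax(state, 0)
}

#' Reaction rate vector
#'
#' Evaluates each reaction's rate law (nM/min) at the given state. Binding
#' steps (`PAK_BIND`, `SEQ_BIND`) report the net forward flux.
#'
#' @param state named state vector over [species_names()].
#' @param network an `rr_network`.
#' @return Named numeric vector over [reaction_names()].
#' @export
rate_vector <- function(state, network) {
  x <- validate_state(state)
  k <- network$kinetics
  u <- network$u
  v <- c(
    RAC_ACT    = k[["Vb_racgef"]] * x[["Rac1_GDP"]] / (k[["Km_r1"]] + x[["Rac1_GDP"]]),
    RAC_DEACT  = (k[["kcat_gap"]] * x[["GAPa"]] + k[["Vb_racgap"]]) *
                 x[["Rac1_GTP"]] / (k[["Km_r2"]] + x[["Rac1_GTP"]]),
    RHO_ACT    = (k[["kcat_gef"]] * x[["GEFH1"]] + k[["Vb_rhogef"]]) *
                 x[["RhoA_GDP"]] / (k[["Km_r3"]] + x[["RhoA_GDP"]]),
    RHO_DEACT  = k[["Vb_rhogap"]] * x[["RhoA_GTP"]] / (k[["Km_r4"]] + x[["RhoA_GTP"]]),
    PAK_BIND   = k[["kon_pak"]] * x[["Rac1_GTP"]] * x[["iPAK"]] -
                 k[["koff_pak"]] * x[["cPAK"]],
    PAK_AUTOPH = k[["k_auto"]] * x[["cPAK"]],
    PAK_DEPH   = k[["V_ppase"]] * x[["pPAK"]] / (k[["Km_p"]] + x[["pPAK"]]),
    GEF_PHOS   = k[["kcat_pakgef"]] * x[["pPAK"]] * x[["GEFH1"]] /
                 (k[["Km_g"]] + x[["GEFH1"]]),
    GEF_DEPH   = k[["V_gppase"]] * x[["pGEFH1"]] / (k[["Km_gp"]] + x[["pGEFH1"]]),
    SEQ_BIND   = k[["kon_14"]] * x[["pGEFH1"]] * x[["F1433"]] -
                 k[["koff_14"]] * x[["pGEFH1_1433"]],
    GAP_ACT    = k[["kcat_rho"]] * x[["RhoA_GTP"]] * x[["GAPi"]] /
                 (k[["Km_ga"]] + x[["GAPi"]]),
    GAP_DEACT  = k[["V_gapoff"]] * x[["GAPa"]] / (k[["Km_gd"]] + x[["GAPa"]]),
    INH_BIND   = k[["kon_i"]] * u * x[["iPAK"]],
    INH_UNBIND = k[["koff_i"]] * x[["iPAK_I"]]
  )
  v[reaction_names()]
}

#' Right-hand side of the model ODE
#'
#' Time derivative of every species (nM/min), computed as the stoichiometry
#' matrix times the rate-law vector. This reference implementation mirrors
#' the compiled C right-hand side used by the integrator; the two are kept
#' in exact agreement (tested on random states).
#'
#' @inheritParams rate_vector
#' @return Named numeric vector of d(concentration)/dt over
#'   [species_names()].
#' @export
#' @examples
#' nw <- build_network(default_abundances(), default_kinetics(), u = 0)
#' rhs(state_inactive(nw), nw)
rhs <- function(state, network) {
  v <- rate_vector(state, network)
  dx <- as.numeric(network$stoichiometry %*% v)
  names(dx) <- species_names()
  dx
}

#' Moiety totals of a state
#'
#' Sums each conserved protein over its member species. Along any
#' trajectory these totals are invariants of the dynamics.
#'
#' @param state named state vector over [species_names()].
#' @return Named numeric vector over the six abundance fields.
#' @export
moiety_totals <- function(state) {
  x <- validate_state(state)
  vapply(moiety_members(), function(members) sum(x[members]), numeric(1))
}

#' Canonical initial states
#'
#' `state_inactive()` puts every moiety in its inactive/unmodified form
#' (GTPases GDP-bound, PAK and the GAP inactive, GEF-H1 unphosphorylated,
#' 14-3-3 free). `state_active()` is the mirror image with every moiety
#' fully activated/modified. These are the deterministic corner states used
#' to seed multi-start steady-state searches.
#'
#' @param network an `rr_network`.
#' @return Named state vector consistent with the network's moiety totals.
#' @export
state_inactive <- function(network) {
  ab <- network$abundances
  x <- setNames(numeric(14), species_names())
  x["Rac1_GDP"] <- ab[["rac1_tot"]]
  x["RhoA_GDP"] <- ab[["rhoa_tot"]]
  x["iPAK"]     <- ab[["pak_tot"]]
  x["GEFH1"]    <- ab[["gefh1_tot"]]
  x["F1433"]    <- ab[["s1433_tot"]]
  x["GAPi"]     <- ab[["racgap_tot"]]
  x
}

#' @rdname state_inactive
#' @export
state_active <- function(network) {
  ab <- network$abundances
  x <- setNames(numeric(14), species_names())
  x["Rac1_GTP"] <- ab[["rac1_tot"]]
  x["RhoA_GTP"] <- ab[["rhoa_tot"]]
  x["pPAK"]     <- ab[["pak_tot"]]
  x["pGEFH1"]   <- ab[["gefh1_tot"]]
  x["F1433"]    <- ab[["s1433_tot"]]
  x["GAPa"]     <- ab[["racgap_tot"]]
  x
}

# mixed corners targeting the two physiological attractor patterns:
# high-Rac/low-Rho (PAK on, GEF suppressed) and low-Rac/high-Rho
state_low_rho <- function(network) {
  ab <- network$abundances
  x <- setNames(numeric(14), species_names())
  x["Rac1_GTP"] <- ab[["rac1_tot"]]
  x["RhoA_GDP"] <- ab[["rhoa_tot"]]
  x["pPAK"]     <- ab[["pak_tot"]]
  x["pGEFH1"]   <- ab[["gefh1_tot"]]
  x["F1433"]    <- ab[["s1433_tot"]]
  x["GAPi"]     <- ab[["racgap_tot"]]
  x
}

state_high_rho <- function(network) {
  ab <- network$abundances
  x <- setNames(numeric(14), species_names())
  x["Rac1_GDP"] <- ab[["rac1_tot"]]
  x["RhoA_GTP"] <- ab[["rhoa_tot"]]
  x["iPAK"]     <- ab[["pak_tot"]]
  x["GEFH1"]    <- ab[["gefh1_tot"]]
  x["F1433"]    <- ab[["s1433_tot"]]
  x["GAPa"]     <- ab[["racgap_tot"]]
  x
}

# Rescale a state onto new moiety totals (used by abundance sweeps with
# state carry-over): each moiety's members are scaled proportionally; a
# moiety whose old total is zero is placed entirely in its inactive form.
project_state <- function(state, network) {
  x <- validate_state(state)
  ab <- network$abundances
  base <- c(rac1_tot = "Rac1_GDP", rhoa_tot = "RhoA_GDP", pak_tot = "iPAK",
            gefh1_tot = "GEFH1", s1433_tot = "F1433", racgap_tot = "GAPi")
  mm <- moiety_members()
  for (m in names(mm)) {
    # members shared between moieties (cPAK, pGEFH1_1433) were already
    # scaled by the first owner; re-scaling per moiety would break the
    # other total, so shared species follow their first moiety and the
    # second moiety absorbs the difference in its base species.
    tot_old <- sum(x[mm[[m]]])
    tot_new <- ab[[m]]
    if (tot_old > 0) {
      x[mm[[m]]] <- x[mm[[m]]] * (tot_new / tot_old)
    } else {
      x[mm[[m]]] <- 0
      x[base[[m]]] <- tot_new
    }
  }
  # repair cross-moiety couplings: fix shared species, rebalance bases
  for (m in names(mm)) {
    d <- ab[[m]] - sum(x[mm[[m]]])
    x[base[[m]]] <- max(0, x[base[[m]]] + d)
  }
  x
}
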