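# shared fixtures: networks and oracles built in code

default_network <- function(u = 0) {
  build_network(default_abundances(), default_kinetics(), u = u)
}

# all rate constants zero (Michaelis constants kept positive)
zero_kinetics <- function() {
  k <- setNames(rep(0, length(kinetics_names())), kinetics_names())
  k[grep("^Km_", names(k))] <- 50
  kinetics(k)
}

# no RhoA -> RacGAP coupling: the double-negative loop is broken, the
# inhibitor dose response is graded (monostable everywhere)
monostable_kinetics <- function() {
  k <- unclass(default_kinetics())
  k["kcat_rho"] <- 0
  kinetics(k)
}

# random network: abundances uniform in the scan box, kinetics jittered
# log-uniformly within a factor of `spread` of the defaults
random_network <- function(seed, spread = 1.5, u_max = 1000) {
  set.seed(seed)
  ab <- unclass(default_abundances())
  ab[sampled_axes()] <- runif(5, 50, 1000)
  k <- unclass(default_kinetics())
  rate_pars <- setdiff(kinetics_names(), grep("^Km_", kinetics_names(),
                                              value = TRUE))
  k[rate_pars] <- k[rate_pars] * exp(runif(length(rate_pars),
                                           -log(spread), log(spread)))
  build_network(structure(ab, class = "rr_abundances"), kinetics(k),
                u = runif(1, 0, u_max))
}

# random feasible state consistent with the network's moiety totals
random_state <- function(network, seed) {
  set.seed(seed)
  ab <- network$abundances
  l <- runif(8)
  rac_gtp <- l[1] * ab[["rac1_tot"]]
  cpak <- l[2] * min(ab[["rac1_tot"]] - rac_gtp, ab[["pak_tot"]])
  ppak <- l[3] * (ab[["pak_tot"]] - cpak)
  ipak_i <- l[4] * (ab[["pak_tot"]] - cpak - ppak)
  rho_gtp <- l[5] * ab[["rhoa_tot"]]
  seq14 <- l[6] * min(ab[["gefh1_tot"]], ab[["s1433_tot"]])
  pgef <- l[7] * (ab[["gefh1_tot"]] - seq14)
  gapa <- l[8] * ab[["racgap_tot"]]
  z <- c(rac_gtp, rho_gtp, cpak, ppak, ipak_i, pgef, seq14, gapa)
  x <- rhoswitch:::.full_state(z, network)
  pmax(x, 0)
}

# brute-force attractor census: integrate many random starts to their
# long-time limits and deduplicate; independent of find_steady_states'
# polishing and saddle machinery
brute_force_stable_states <- function(network, n_starts = 200, seed = 1,
                                      dedup_rtol = 1e-3) {
  scale <- max(sqrt(sum(as.numeric(network$abundances)^2)), 1)
  found <- list()
  for (i in seq_len(n_starts)) {
    x0 <- random_state(network, seed * 10000 + i)
    rl <- rhoswitch:::.relax(network, x0, t_max = 5e4)
    if (!rl$converged) next
    # guard against landing on a saddle's stable manifold: nudge and relax
    # once more; true attractors are unaffected
    set.seed(seed * 10000 + i)
    nudged <- rhoswitch:::project_state(
      pmax(rl$state * (1 + 0.01 * runif(14, -1, 1)), 0), network)
    rl2 <- rhoswitch:::.relax(network, nudged, t_max = 5e4)
    if (!rl2$converged) next
    y <- rl2$state
    new <- TRUE
    for (k in found) {
      if (sqrt(sum((y - k)^2)) / scale < dedup_rtol) { new <- FALSE; break }
    }
    if (new) found <- c(found, list(y))
  }
  found
}

state_dist <- function(a, b) sqrt(sum((a - b)^2))
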