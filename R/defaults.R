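#' Default total abundances
#'
#' Reference totals (nM) used throughout the package, chosen inside the
#' 0-1000 nM sampling box: abundant GTPases and kinase (Rac1 400, RhoA 500,
#' PAK 600, 14-3-3 500 nM), a scarcer GEF-H1 pool (80 nM; the GEF is the
#' limiting node of the RhoA arm and bistability requires it to be low
#' relative to PAK and 14-3-3), and a fixed Rac GAP moiety of 200 nM (the
#' GAP total is model-internal and not part of the sampled axes). All
#' values are configurable; measured cell-line-specific totals should be
#' substituted when available.
#'
#' @return An `rr_abundances` vector.
#' @export
default_abundances <- function() {
  abundances(rac1_tot = 400, rhoa_tot = 500, pak_tot = 600,
             gefh1_tot = 80, s1433_tot = 500, racgap_tot = 200)
}

#' Default kinetic constants (calibrated to the bistable regime)
#'
#' The shipped constants are the output of [calibrate_bistable_defaults()]
#' run on [default_kinetics_box()] with `seed = 1` at the default
#' abundances: the box midpoint qualifies, giving an inhibitor dose
#' response with distinct up- and down-switch thresholds (T2 < T1) at
#' u = 0 monostable low-RhoA resting state. They are a calibrated reference
#' set for exploring the network's dynamics, not measured rate constants.
#'
#' @return An `rr_kinetics` vector.
#' @export
default_kinetics <- function() {
  kinetics(
    Vb_racgef = 300, Km_r1 = 100,
    kcat_gap = 3.9, Vb_racgap = 6, Km_r2 = 100,
    kcat_gef = 12, Vb_rhogef = 3, Km_r3 = 50,
    Vb_rhogap = 450, Km_r4 = 50,
    kon_pak = 0.006, koff_pak = 15, k_auto = 30,
    V_ppase = 150, Km_p = 50,
    kcat_pakgef = 2.4, Km_g = 600,
    V_gppase = 450, Km_gp = 600,
    kon_14 = 0.0075, koff_14 = 1.5,
    kcat_rho = 3, Km_ga = 100,
    V_gapoff = 400, Km_gd = 100,
    kon_i = 0.0045, koff_i = 0.9
  )
}

#' Default admissible box of kinetic constants
#'
#' The search box handed to [calibrate_bistable_defaults()]: each constant
#' may vary 2.5-fold up or down around the calibrated defaults. Its
#' geometric midpoint is the calibrated default set itself.
#'
#' @param spread multiplicative half-width of the box.
#' @return List with named vectors `lo` and `hi`.
#' @export
default_kinetics_box <- function(spread = 2.5) {
  k <- as.numeric(default_kinetics())
  names(k) <- kinetics_names()
  list(lo = k / spread, hi = k * spread)
}

#' Default inhibitor grid for calibration and hysteresis checks
#'
#' @param n number of grid points.
#' @param u_max top of the grid (nM).
#' @return Numeric grid from 0 to `u_max`.
#' @export
default_u_grid <- function(n = 40, u_max = 1500) {
  seq(0, u_max, length.out = n)
}
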