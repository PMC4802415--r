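---
title: "Modeling bistable Rac1-RhoA signaling under PAK inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bistable Rac1-RhoA signaling under PAK inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhoswitch)
```

## The model

The small GTPases Rac1 and RhoA antagonize each other through their
effector kinases. In this model the mutual inhibition is carried by two
arms:

* **Rac1 → PAK ⊣ GEF-H1 → RhoA.** Rac1-GTP binds PAK's CRIB domain
  (mass action, `kon_pak`/`koff_pak`); the complex autophosphorylates
  intramolecularly (`k_auto`), releasing Rac1-GTP and active pPAK. pPAK
  phosphorylates the RhoA exchange factor GEF-H1 on inhibitory sites
  (`kcat_pakgef`, `Km_g`), and phospho-GEF-H1 is additionally sequestered
  by 14-3-3 (`kon_14`/`koff_14`). Only free phospho-GEF-H1 is
  dephosphorylated (`V_gppase`, `Km_gp`): 14-3-3 binds the phospho-motif
  and thereby protects it.
* **RhoA → RacGAP ⊣ Rac1.** RhoA-GTP activates a pool of Rac GAPs
  (`kcat_rho`, `Km_ga`; deactivation `V_gapoff`, `Km_gd`), standing in for
  the ROCK-dependent activation of GAPs such as ARHGAP22 and FilGAP, and
  active GAP stimulates Rac1-GTP hydrolysis (`kcat_gap`, `Km_r2`).

Both GTPase cycles also carry basal, Michaelis-Menten-type activation and
deactivation fluxes (`Vb_*`, `Km_*`). A small-molecule PAK inhibitor binds
the inactive kinase conformation, competing with Rac1-GTP for PAK
(`kon_i`/`koff_i`); already-active pPAK is untouched. The free
intracellular inhibitor `u` is an external forcing, not a conserved
species: small molecules equilibrate across the membrane within minutes, so
depletion of the free pool by binding is neglected.

This yields 14 species, 14 reactions and six conserved moieties (Rac1,
RhoA, PAK, GEF-H1, 14-3-3, RacGAP); units are nM and minutes throughout.
The double-negative loop is a positive feedback circuit overall, and the
zero-order character of the GTPase and GAP cycles supplies the
ultrasensitivity that makes it bistable in a wide parameter region.

Two structural choices deserve note. PAK autophosphorylation releases
Rac1-GTP (the complex is treated as catalytic for Rac1), which keeps Rac1
available for further signaling. And the Rac GAP pool is an explicit
conserved moiety with a fixed default total (200 nM) even though stability
scans sample only the other five totals; this keeps the RhoA→Rac1 arm
mechanistic rather than phenomenological.

## Default abundances and calibrated kinetics

Measured, cell-line-specific protein totals belong in a configuration file
(`read_model_config()`); the shipped defaults are reference values inside
the 0–1000 nM scan box: abundant GTPases, kinase and adaptor (Rac1 400,
RhoA 500, PAK 600, 14-3-3 500 nM) and a scarce GEF-H1 pool (80 nM). GEF-H1
is deliberately the limiting node: bistability of this circuit requires the
PAK/14-3-3 suppression capacity to exceed the GEF-H1 pool, so the resting
(no inhibitor) cell sits in a *single* high-Rac1/low-RhoA state, which is
the experimentally observed starting condition of motile cells.

No measured rate constants are available for the assembled network, so the
kinetic defaults are produced by `calibrate_bistable_defaults()`: a
deterministic random search over a log-uniform box that returns the first
constant set whose inhibitor dose response is hysteretic (distinct up- and
down-switch thresholds). The shipped box is centred on the shipped
constants, so the calibration reproduces them from its midpoint; they were
selected to satisfy, simultaneously,

* a monostable low-RhoA resting state at `u = 0`;
* a bistable inhibitor window (about 100–865 nM at the defaults, with the
  up-switch threshold T1 ≈ 865 nM and down-switch threshold T2 ≈ 96 nM);
* hysteresis of RhoA-GTP in the *total Rac1 abundance* at `u = 0`
  (window ≈ 90–185 nM);
* switching kinetics fast enough that 20–80 min incubations approach the
  branch steady states (all first-order rates are of order 1–30 min⁻¹,
  within typical ranges for signaling enzymes);
* abundance-space associations in which bistable parameter sets show high
  RhoA, PAK and 14-3-3 but low GEF-H1 totals.

They are a calibrated reference parameterization, not measurements.

## Steady states and stability

Six conservation laws reduce the system to eight independent variables.
`find_steady_states()` seeds relaxation runs from four deterministic
corners (all-inactive, all-active, and the two mixed corners matching the
low-RhoA and high-RhoA activity patterns) plus Latin-hypercube starts on
the moiety-feasible region (default 50), integrates each to quiescence with
a stiff solver (compiled right-hand side, `lsoda`), and polishes the
endpoints with a damped Levenberg–Marquardt root finder on the reduced
system. Quiescence means `max |dx/dt| < 1e-8` nM/min or a relative state
drift below 1e-9 per 100 min; a trajectory that stays bounded but never
settles by `t = 1e5` min marks the network as dynamics class `other`
(an oscillation screen — none of the calibrated regimes oscillate, but
sampled corners of parameter space occasionally stall the integrator,
which is reported the same way rather than crashing a scan).

Duplicates are merged at relative L2 distance 1e-6. Saddle points are found
by bisecting the straight segment between each pair of stable states on
basin membership and polishing from the boundary; inside the bistable
window this reliably yields the intermediate unstable state, giving the
expected odd fixed-point count (1 or 3).

Stability is classified from the Jacobian of the *reduced* system (central
differences, relative step 1e-6): stable if the leading eigenvalue's real
part is below −1e-6 min⁻¹, unstable above +1e-6, marginal otherwise. The
reduced spectrum equals the full 14-dimensional spectrum minus the six
zero modes contributed by the conservation laws, so the labels do not
depend on which species are eliminated; the test suite verifies this
correspondence numerically.

`dynamics_class()` uses a smaller multi-start budget (12 Latin-hypercube
starts plus the corners). With the branch-targeted corners this detects
both attractors of every bistable regime we have examined; the budget is a
per-cell cost knob for region maps and abundance scans, not a statistical
estimate.

## Hysteresis sweeps and region maps

`sweep1d()` implements continuation by state carry-over: the relaxed state
at one grid point initializes the next. This mirrors the experimental
pretreat/washout logic and is what exposes hysteresis; pseudo-arclength
continuation is intentionally out of scope. When an abundance (a conserved
total) is swept, the carried state is rescaled proportionally onto the new
moiety totals.

`hysteresis()` detects a switch as a grid interval whose readout step
exceeds five times the median inter-point step, with a floor of 5% of the
branch's range so that numerically flat branches are never flagged;
contiguous flagged intervals count as one jump (a grid point can land
mid-transition), while two separate clusters raise an error advising a
finer grid. T1 is the midpoint of the forward-sweep jump interval, T2 of
the backward one, and the bistable flag requires jumps in both directions
at distinct locations. Branches are reported in ascending grid order, so a
backward-traverse drop appears as a positive grid-order step. For
threshold verification independent of sweeping, `bistable_range()` bisects
on the stable-state count to relative parameter resolution 1e-3; sweep
thresholds agree with it to within one grid step.

`region2d()` simply classifies every cell of a 2D grid independently, so
results do not depend on evaluation order and rows can be cross-checked
against 1D sweeps.

## Abundance-space scans

`scan_abundance_space()` samples the five totals uniformly (Latin
hypercube behind a flag) in the 0–1000 nM box at `u = 0` — the inhibitor
is a perturbation applied later, not part of the resting-cell stability
landscape — and classifies each set. At the calibrated kinetics roughly
4–5% of the box is bistable; `association_summary()` contrasts bistable
versus monostable sets per axis by median difference plus a Wilcoxon
rank-sum statistic, and `parallel_coords_table()` normalizes the sampled
coordinates to the box (not to the realized sample) for
parallel-coordinate displays. Sets classified `other` are excluded from
contrasts and reported separately. The package default scan size for
summary statistics is 2,000 sets, which resolves the median contrasts'
signs; much larger scans (the methodology scales linearly) sharpen the
same picture.

## Dosing protocols

`make_schedule()` encodes the two experimental arms: naive (one segment,
default 40 min at the test dose) and pretreated (20 min at the maximal
dose, then washout into 20 min at the test dose). Within a segment the
intracellular free inhibitor relaxes exponentially toward the applied dose
with rate ln 2 / `t_half`; the default half-life of 3.5 min is the midpoint
of the measured 2–5 min intracellular clearance range. With `t_half` = 5
min the residual 10 min after washout is exactly 25%. The longer
imaging-style incubations (80 min naive, 60 min post-washout) are a preset
of the same parameters.

The dose axis is the *model's* free intracellular inhibitor in nM; the
mapping to an extracellular micromolar dose of a specific compound is a
single configurable scale factor and is deliberately left free.

One kinetic observation matters for interpreting the biochemical-duration
arms: after a high-dose pretreatment, clearing the inhibitor from ~3000 nM
to below the down-switch threshold takes ~15 min at `t_half` = 3.5 min, so
a 20-min post-washout readout at dose 0 still shows elevated RhoA-GTP even
though the dose-0 state is monostable — a transient "kinetic memory" on
top of the true steady-state hysteresis. With the 60-min imaging preset the
arms coincide at dose 0 and at saturating dose, and differ by nearly the
full dynamic range inside the window.

## Synthetic cell populations

`sample_population()` draws per-cell totals independently per axis from
lognormal distributions with median equal to the nominal value; protein
copy numbers are positive and right-skewed, and a default CV of 20% is
typical of mammalian protein expression variability (the acceptance
analyses use this value; the generator accepts any CV). Readouts are raw
terminal RhoA-GTP or Rac1-GTP concentrations with multiplicative lognormal
observation noise (densitometry- and immunofluorescence-like); the mapping
from GTPase activity to downstream markers is deliberately
identity-plus-noise, because downstream readouts integrate additional
signaling this model does not describe. Branch selection is purely
deterministic per cell (carried initial conditions); stochastic chemical
switching is out of scope.

Because each cell's switching thresholds move with its protein totals, a
population dosed inside the bistable window splits between branches and the
readout distribution becomes bimodal, while doses far below T2 or far above
T1 (beyond the threshold spread of essentially all cells) give unimodal
distributions. `bimodality_test()` fits one- and two-component Gaussian
mixtures to log readouts and calls bimodality when the two-component model
improves the (smaller-is-better) BIC by more than 10 *and* the component
means are over two pooled standard deviations apart; the moment-based
bimodality coefficient is reported as secondary, descriptive evidence.
Single-cell data can show more than two subpopulations; only two-component
structure is modeled here.

## Parameter recovery

`synthetic_dose_response()` emulates replicate densitometry tables (mean,
SD, n per dose and arm). `fit_parameters()` minimizes the weighted squared
deviation between those means and the model's protocol readouts over up to
four kinetic constants, in log-parameter space, by multi-start
Levenberg–Marquardt (box midpoint first, then log-uniform starts; the
inner steady-state polish deliberately uses the package's own
Levenberg–Marquardt implementation so that nested optimizations cannot
interact). A flat-profile diagnostic warns when a ±20% perturbation of an
estimate changes the objective by less than a 1e-4 relative margin, which
flags structurally non-identifiable designs such as fitting an
inhibitor-binding constant from untreated data. On 5%-noise synthetic data
over eight doses and both arms, `kcat_gef` and `kon_i` are recovered within
a few percent.

## Numerical choices and problem sizes

* Integration: `lsoda`, rtol = atol = 1e-8 (1e-10 in cross-checks), compiled
  C right-hand side; trajectories are verified to conserve all six moiety
  totals to relative 1e-6 and to remain nonnegative without solver clipping.
* Steady-state tolerance 1e-8 nM/min; dedup 1e-6 relative L2; stability
  margin 1e-6 min⁻¹.
* Jump detection: 5 × median step with a 5% range floor; bisection
  refinement of windows to 1e-3 relative resolution.
* The shipped analyses use desk-scale sizes chosen to resolve each
  qualitative claim: 2,000-set scans, 20 × 20 region maps, 40-point
  inhibitor grids, 31-point Rac1 grids, 500-cell populations, and a
  20-network steady-state-oracle comparison at 200 brute-force starts each.

## Limitations

* The model omits additional positive feedback (e.g. Cool-2-mediated
  Rac1–PAK feedback, PAK-independent Rac1 self-activation) and GDI cycling;
  these are expected to widen, not create, the bistable region.
* No spatial resolution and no stochastic kinetics: a cell is a well-mixed
  compartment that occupies exactly one branch.
* The inhibitor axis is in model nM; absolute comparisons to extracellular
  doses of a real compound require an independently estimated scale factor.
* 14-3-3 is modeled with a single GEF-H1 binding site.
* The Rac1-abundance bistable window at the calibrated defaults is narrow
  (about 90–185 nM) compared with the inhibitor window; grids finer than
  ~10 nM are needed to resolve its thresholds accurately.
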