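---
title: "Methods: VEGF-Notch signaling on ligand micropatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VEGF-Notch signaling on ligand micropatterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notchsprout)
```

## The biological question and the model

Sprouting angiogenesis is led by migratory *tip* cells and consolidated by
proliferative *stalk* cells; the choice between the two fates is made by
VEGF-Notch crosstalk. VEGF activates VEGFR; activated VEGFR up-regulates
the Notch ligand Dll4; Dll4 on one cell trans-activates Notch1 on its
neighbours; the released NICD down-regulates VEGFR and Dll4 and up-regulates
Notch1 and the second ligand Jag1. This closes the classical lateral
inhibition loop: a prospective tip cell suppresses the tip fate in its
neighbours. Fringe glycosyltransferases, themselves NICD-induced, bias
receptor-ligand binding so that Dll4-Notch1 signaling strengthens while
Jag1-Notch1 signaling weakens.

Printing stripes of immobilized ligand under the cells adds one exogenous
input: cells standing on a line see an additional pool of substrate-bound
ligand that trans-activates their Notch1 exactly as a neighbour's ligand
would. The package models a periodic row of `M` cells (default 12) spanning
the repeat unit of the stripe pattern, with half the cells on lines (two
contiguous blocks at the row ends, i.e. half of each of the two flanking
lines). Six species per cell — free Notch1, Dll4, Jag1, NICD, free VEGFR,
activated VEGFR — evolve under shifted-Hill regulated production,
cis-inhibition (`k_C`), trans-activation (`k_T`), and first-order decay
(`gamma` for free species, `gamma_S` for the activated species). See
`?row_rhs` for the exact equations. One asymmetry of the printed equations
is kept deliberately: the trans loss of free ligand to neighbouring
receptors enters as `k_T * N_ext` without a Fringe factor, while the
receptor equation carries Fringe factors on both cis and trans binding.

Fringe appears only through the factors `H(I, lambda_F_D)` and
`H(I, lambda_F_J)`; it is not a separate state variable, because its effect
on the binding rates is what matters and its own dynamics would add a state
the readouts never see.

Both `D_line` and `J_line` live on every layout even though the stripe
experiments use one ligand at a time; the experiment drivers enforce
single-ligand arms, while the core stays forward-compatible at no cost.

## Parameters, units, defaults

All contents are in molecules, times in hours, production rates in
molecules/hour, binding rates in 1/(molecule x hour). The default set
(`model_parameters()`, also shipped as
`inst/extdata/default_params.yaml`) follows the established
Notch-Delta-Jagged-VEGF tip/stalk model family for endothelial cells:
degradation `gamma = 0.1`/h for free species and `gamma_S = 0.5`/h for NICD
and activated VEGFR, cis-inhibition `k_C = 5e-4`, trans-activation
`k_T = 2.5e-5` 1/(molecule x hour), a NICD threshold of `I0 = 200`
molecules for all NICD-mediated regulation, and fold-changes encoding the
regulatory signs: NICD up-regulates Notch1 and Jag1 (`lambda = 2`),
fully down-regulates Dll4 and VEGFR (`lambda = 0`), activated VEGFR
up-regulates Dll4 (`lambda = 2`), and Fringe triples Dll4-Notch1 binding
(`lambda_F_D = 3`) while reducing Jag1-Notch1 binding tenfold
(`lambda_F_J = 0.1`) — an order-of-magnitude asymmetry consistent with the
strong reported inhibition of Jagged signaling by Fringe.

The magnitudes that anchor the VEGF arm (`V_ext = 20000` molecules,
`VR0 = 200` molecules/h, `V0 = 150` molecules) and the production rates
(`N0 = 1200`, `D0 = 400`, `J0 = 800`) were fixed once, by requiring the
model to reproduce the documented behaviour of the system at the calibrated
line content of 3000 molecules:

* an unpatterned row relaxes to a hybrid-dominated population (activated
  VEGFR inside the 100-300 molecule band) with Ef_cs near 50%;
* Dll4 lines at 3000 molecules drive on-line cells to the stalk phenotype
  within 12 h (Ef_cs near 100%);
* Jag1 lines at 3000 molecules barely shift Ef_cs at 12 h but act strongly
  by 24 h;
* homogeneously Dll4-coated substrates elicit a larger Jag1 expression
  response at 6 h than Jag1-coated ones, which in turn exceed the uncoated
  control — the ordering used for calibration.

These constraints mirror the homogeneous-coating calibration that selects
`D_line = J_line = 3000` in the first place; they were applied once to fix
the defaults, which have not been revisited since. Every value can be
overridden programmatically or in a config file, and the config loader
rejects unknown keys so typos cannot silently fall back to defaults.

Phenotype thresholds (100 and 300 molecules of activated VEGFR) are part of
the phenotyping rule, not the kinetics; a final value of exactly 0 counts
as stalk, and both interval boundaries count as hybrid, so the three labels
partition the axis.

## Randomness and ensembles

Finite-horizon solutions depend on initial conditions, so every experiment
is a Monte-Carlo ensemble (default 10,000 replicates). Initial contents are
drawn uniformly and independently, strictly inside `(0, 6000)` molecules
for `N, D, J, V_R` and `(0, 600)` for `I, V` — the minimal-assumption
distribution on the stated box, emulating the random mix of phenotypes of
VEGF-exposed cultures before seeding.

All draws for an ensemble happen up-front from the master seed, in a fixed,
documented order (replicate outermost, then cells, then species in the
order `N, D, J, I, VR, V`). Because the integrator is deterministic, this
makes results independent of replicate execution order, and it implements
common random numbers for free: two arms of a comparison run with the same
seed share initial conditions replicate by replicate, so sweep curves and
sensitivity deltas are differences between positively correlated
estimators. A design with per-replicate counter-based substreams would
allow streaming replicates without materializing the draws; the up-front
draw was chosen instead because one ensemble's initial conditions occupy
only `6 * M * n` doubles (about 6 MB at the default sizes), and the ordering
contract is easier to state and test.

`Ef_cs` is undefined when a replicate has no sprouting cell at all; such
replicates propagate as `NA`, are counted, and are excluded from summary
statistics — never coerced to 0 or 100, which would bias exactly the
regimes (strong ligand, many on-line cells) where they occur.

## Numerics

The production integrator is the explicit Euler scheme with `dt = 0.01` h,
applied for exactly `round(t_fin / dt)` steps — the same scheme in the
pure-R reference (`integrate_row()`) and in the compiled ensemble kernel;
the two agree to machine precision and the test suite holds the scheme
against an adaptive high-order reference (`deSolve::lsoda` at tight
tolerance): the norm-wise relative error of the final state is a few
`1e-4` at the default step. Per-species errors are larger (up to about 1%)
for the fastest-relaxing species, which is expected for a first-order
scheme and irrelevant to phenotype calls that sit far from the thresholds;
halving `dt` leaves ensemble means unchanged within Monte-Carlo error.

Negative or non-finite values abort the integration with the replicate,
step and species named. With the default parameters the scheme is stable,
so negativity indicates a misconfiguration (e.g. a destabilizing `dt`), and
clamping would mask it.

On small rings the lateral-inhibition loop has the textbook consequence
that the uniform steady state can be unstable: a two-cell ring relaxes to
an alternating high-NICD/low-NICD pair. The test suite verifies both fixed
points against an independent nonlinear root solver. At the study horizon
of 12 h and `M = 12`, unpatterned rows have not established such patterns
and end hybrid-dominated, which is the regime the statistic operates in.

## The synthetic point patterns

`generate_point_pattern()` emulates nuclei centroid tables over the
100 um / 100 um stripe geometry under the three qualitative regimes —
random, positive (on-line enrichment), negative (between-line enrichment) —
interpolated into a quantitative family: the off-stripe probability is
`0.5 + 0.5 * strength` (negative), `0.5 - 0.5 * strength` (positive) or
`0.5` (random), with positions uniform within the chosen region. This
gives the spatial statistic a tunable ground truth (`Ef_cs` converges to
`100 * p_off` by the law of large numbers). Points are independent: the
generator does not emulate nuclear exclusion, cell clustering or sprout
connectivity, so passing tests validate the counting statistic and its
geometry handling, not any spatial-process model of real monolayers.
Centroids exactly on a stripe edge count as on-line (closed stripes,
half-open gaps) — an arbitrary but fixed tie-break that keeps counts
reproducible.

## Experiment drivers

* `calibrate_coating()` — homogeneous coating means every cell is
  on-ligand (a coated well has no off-pattern region), 6 h horizon. The
  "Jag1 expression" readout is free Jag1 averaged over cells and
  replicates: the model carries no transcript, and free Jag1 is the
  quantity NICD up-regulates; fold-change over the uncoated arm mirrors
  qPCR normalization.
* `ligand_density_sweep()` — default grid 0-6000 molecules in steps of
  500, bracketing the calibrated 3000; the grid is configurable since no
  canonical grid exists.
* `time_sweep()` — end times 6-24 h; one integration per replicate to the
  largest horizon supplies all earlier horizons as checkpoints, so the
  grid shares trajectories exactly. The row size stays at `M = 12` across
  end times.
* `cell_count_sweep()` — on-line cells between 0 and `M`, always as two
  edge blocks, as symmetric as possible.
* `sensitivity_analysis()` — one-at-a-time multiplicative perturbations of
  every kinetic/Hill parameter, both `x1.1` and `x0.9` with common seeds
  (the direction is not prescribed, so both are computed and the largest
  magnitude reported), against the ligand-type-switch reference at equal
  line density.

Every experiment table carries a manifest (parameter hash, seed, grid,
settings echo) sufficient to regenerate it bit-identically.

## Problem sizes used in the shipped checks

The package's own test suite runs the full-size checks where the claim
depends on `n` (the unpatterned control at 10,000 replicates) and scaled
ensembles elsewhere (2,000 replicates for the headline line ensembles,
1,000 per sensitivity arm, 400 for sweep shapes), sizes at which the
Monte-Carlo standard error of a mean Ef_cs is a few tenths of a percentage
point — comfortably inside the stated tolerances. The acceptance script
recomputes the headline ensembles at the study size of 10,000.

## Known limitations

The model inherits the scope of its family: a 1-D periodic row (no 2-D
lattice), deterministic mass-action/Hill chemistry (no stochastic
bursting), a single Notch receptor and two ligands, constant uniform
external VEGF (no gradients), and no filopodia, cell movement or shape
change. It describes the initial fate decision of cells still in their
seeding positions, which is why the default horizon is 12 h; asymptotic
states of the same equations (for example the alternating patterns above)
are outside the regime the statistic is designed for. The point-pattern
generator, likewise, is a ground-truth device for the counting statistic,
not a model of endothelial morphology.
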