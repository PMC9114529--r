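# notchsprout

Simulation and analysis of how micropatterned stripes of the Notch ligands
**Dll4** and **Jag1** spatially control endothelial tip/stalk fate selection
during sprouting angiogenesis.

Endothelial cells seeded over ligand-functionalized lines (100 um lines,
100 um spacing) integrate VEGF stimulation with Notch lateral inhibition.
Dll4-coated lines force the cells sitting on them into the non-sprouting
stalk phenotype, confining sprouts to the gaps between lines (*negative
patterning*); Jag1 lines, whose Notch1 activation is slower, barely bias
sprout locations on the experimental time scale. This package implements the
computational side of that system for researchers in vascular biology and
tissue engineering: a multicellular ODE model of VEGF-Notch signaling with
substrate-ligand terms, Monte-Carlo ensembles over random initial protein
contents, phenotype classification, the efficiency-of-controlled-sprouting
statistic, the in-silico calibration and parameter-exploration experiments,
and a synthetic generator for nuclei point patterns over stripe geometries.

## Model

A periodic row of `M` cells (default 12, spanning the region between the
mid-lines of two adjacent stripes; half the cells sit on lines). Each cell
`i` carries free Notch1 (`N_i`), free Dll4 (`D_i`), free Jag1 (`J_i`), NICD
(`I_i`), free VEGFR (`V_R,i`) and activated VEGFR (`V_i`), all in molecules,
with dynamics

```
dN/dt  = N0 H(I, l_I,N) - N [ (kC D + kT D_ext) H(I, l_F,D)
                            + (kC J + kT J_ext) H(I, l_F,J) ] - g N
dD/dt  = D0 H(I, l_I,D) H(V, l_V,D) - D [ kC H(I, l_F,D) N + kT N_ext ] - g D
dJ/dt  = J0 H(I, l_I,J)             - J [ kC H(I, l_F,J) N + kT N_ext ] - g J
dI/dt  = kT N [ D_ext H(I, l_F,D) + J_ext H(I, l_F,J) ] - gS I
dVR/dt = VR0 H(I, l_I,VR) - kT VR V_ext - g VR
dV/dt  = kT VR V_ext - gS V
```

where `H(X, l) = l + (1 - l) / (1 + (X/X0)^n)` is the shifted Hill function
and the external terms average the two neighbours (periodic indexing), with
the substrate contents `D_line` / `J_line` added for cells on a line:

```
N_ext = (N[i-1] + N[i+1]) / 2
D_ext = (D[i-1] + D[i+1]) / 2 + D_line  (if cell i is on a Dll4 line)
J_ext = (J[i-1] + J[i+1]) / 2 + J_line  (if cell i is on a Jag1 line)
```

The system is integrated with the explicit Euler scheme (`dt = 0.01` h, end
time 12 h by default) from random initial conditions (uniform in
`(0, 6000)` molecules for `N, D, J, V_R`, `(0, 600)` for `I, V`). A cell's
phenotype is read from its final activated VEGFR: **stalk** below 100
molecules, **hybrid tip/stalk** in `[100, 300]`, **tip** above 300. The
efficiency of controlled sprouting is

```
Ef_cs = 100 * C_off / (C_off + C_on)   [%]
```

with `C_off` / `C_on` the sprouting (tip + hybrid) cells off / on the lines:
about 50% for random patterning, about 100% when sprouts are confined
between the lines, about 0% when they sit on the lines. The same statistic
applies to nuclei centroid tables over a stripe geometry
(`efcs_from_points()`).

## Worked example

```r
library(notchsprout)
params <- model_parameters()                    # defaults; see vignette
lay    <- pattern_layout(M = 12, d_line = 3000) # calibrated Dll4 lines
print(lay)
#> Pattern layout: M = 12 cells, 6 on lines (D_line = 3000, J_line = 0 molecules)
#>   row: ###......###   (# = on line, periodic)

ens <- run_ensemble(params, lay,
                    simulation_settings(n_replicates = 1000, seed = 42))
print(ens)
#> Ensemble: 1000 replicates, M = 12 (6 on lines), D_line = 3000, J_line = 0
#>   Ef_cs: mean 99.4%, median 100.0%, IQR [100.0, 100.0], P10-P90 [100.0, 100.0]
#>   phenotype fractions on lines:  stalk 0.99, hybrid 0.01, tip 0.00
#>   phenotype fractions off lines: stalk 0.11, hybrid 0.84, tip 0.05
```

The Dll4 lines drive 99% of on-line cells to the stalk phenotype within
12 h while the off-line cells stay mostly hybrid (slowly migrating), so
essentially every sprouting cell lies between the lines: mean Ef_cs of
99.4% — negative patterning. Rerunning with `j_line = 3000` instead leaves
Ef_cs near 56%, close to the unpatterned control (about 50%): Jag1 activates
Notch1 too slowly to reposition sprouts on this time scale.

The spatial statistic works directly on point patterns:

```r
pp <- generate_point_pattern("negative", strength = 0.4, n_points = 400,
                             seed = 1)
efcs_from_points(pp)
#> Ef_cs = 70% (C_off = 280, C_on = 120)
```

A command-line wrapper with subcommands (`simulate`, `ensemble`,
`calibrate`, `sweep-density`, `sweep-time`, `sweep-cells`, `sensitivity`,
`efcs-points`, `synth-points`) is installed at
`system.file("cli", "notchsprout.R", package = "notchsprout")`.

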