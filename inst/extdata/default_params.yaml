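# Default configuration of the VEGF-Notch micropattern signaling model.
#
# Units: production rates molecules/hour; degradation rates 1/hour; binding
# rates 1/(molecule*hour); contents and thresholds molecules; times hours;
# exponents and fold-changes dimensionless.
#
# Provenance: the kinetic core (gamma, gamma_S, k_C, k_T, the NICD Hill
# threshold I0 and the signs/structure of every fold-change: NICD
# up-regulates Notch1 and Jag1, down-regulates Dll4 and VEGFR; activated
# VEGFR up-regulates Dll4; Fringe strengthens Dll4-Notch1 and weakens
# Jag1-Notch1 binding) follows the published Notch-Delta-Jagged-VEGF
# tip/stalk model family for endothelial cells. The VEGF-arm magnitudes
# (V_ext, VR0, V0), the production rates and the Fringe-on-Jag1 fold were
# fixed by the package's homogeneous-coating calibration so that, at the
# calibrated line content of 3000 molecules, unpatterned cells end
# hybrid-dominated (activated VEGFR in the 100-300 molecule band), Dll4
# lines drive on-line cells to the stalk phenotype within 12 h, and Jag1
# lines respond much more slowly. See the methods vignette for the full
# rationale. Every value can be overridden here or programmatically.
metadata:
  package: notchsprout
  version: 0.1.0
  units:
    production: molecules/hour
    degradation: 1/hour
    binding: 1/(molecule*hour)
    contents: molecules
    time: hours
parameters:
  N0: 1200.0      # Notch1 production
  D0: 400.0       # Dll4 production
  J0: 800.0       # Jag1 production
  VR0: 200.0      # VEGFR production
  gamma: 0.1      # degradation of ligands and inactive receptors
  gamma_S: 0.5    # degradation of NICD and activated VEGFR
  k_C: 5.0e-4     # cis-inhibition rate
  k_T: 2.5e-5     # trans-activation rate (also VEGFR activation by VEGF)
  V_ext: 20000.0  # external VEGF content
  I0: 200.0       # Hill threshold, NICD-mediated regulation
  V0: 150.0       # Hill threshold, activated-VEGFR-mediated regulation
  n_N: 2.0
  n_D: 2.0
  n_J: 5.0
  n_F: 2.0
  n_VR: 2.0
  lambda_I_N: 2.0   # NICD up-regulates Notch1
  lambda_I_D: 0.0   # NICD down-regulates Dll4
  lambda_I_J: 2.0   # NICD up-regulates Jag1
  lambda_I_VR: 0.0  # NICD down-regulates VEGFR
  lambda_V_D: 2.0   # activated VEGFR up-regulates Dll4
  lambda_F_D: 3.0   # Fringe strengthens Dll4-Notch1 binding
  lambda_F_J: 0.1   # Fringe weakens Jag1-Notch1 binding
layout:
  M: 12          # cells in the periodic row
  n_on: 6        # half the cells sit on lines (two edge blocks)
  d_line: 0.0    # Dll4 content on the lines
  j_line: 0.0    # Jag1 content on the lines
settings:
  dt: 0.01        # Euler step, hours
  t_fin: 12.0     # end time, hours
  n_replicates: 10000
  seed: 1
  ic_bounds:      # upper bounds of the random initial-condition box
    N: 6000.0
    D: 6000.0
    J: 6000.0
    I: 600.0
    VR: 6000.0
    V: 600.0
  record_every: 1.0
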