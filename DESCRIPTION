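Package: notchsprout
Title: Tip/Stalk Patterning of Endothelial Cells on Notch-Ligand Micropatterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multicellular simulation of VEGF-Notch signaling for endothelial
    cells seeded over micropatterned stripes of the Notch ligands Dll4 or Jag1.
    A periodic row of cells is modelled with per-cell ordinary differential
    equations for free Notch1, Dll4, Jag1, NICD, VEGFR and activated VEGFR,
    with shifted-Hill regulation, cis-inhibition, trans-activation and
    substrate-bound ligand terms for cells sitting on the printed lines.
    Includes seeded Monte-Carlo ensembles over random initial protein contents,
    tip/hybrid/stalk phenotype classification from final VEGFR activation, the
    efficiency-of-controlled-sprouting statistic for simulations and for
    nuclei point patterns, homogeneous-coating calibration, ligand-density,
    end-time and cell-count sweeps, one-at-a-time parameter sensitivity
    analysis, and a synthetic generator for nuclei point patterns over stripe
    geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
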