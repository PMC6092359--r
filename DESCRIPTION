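Package: scramblr
Title: Quantification of Phospholipid Scrambling Kinetics and Groove Dynamics
    in TMEM16 Scramblases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify lipid scrambling and ion-channel activity of
    reconstituted TMEM16-family scramblases, and to analyse the lipid
    translocation pathway in molecular-dynamics trajectories. The assay arm
    implements the analytical three-state Markov model of the dithionite
    bleaching assay (protein-free and scramblase-containing liposome
    populations, slow leak, rate-limited detection, the linear low-activity
    regime) with constrained nonlinear least-squares fitting, impact
    classification of mutants, and end-point chloride flux quantification.
    The trajectory arm computes groove lipid/water occupancy, compartment
    occupancy, residue-lipid contact frequencies, extracellular gate state
    metrics, lipid flip detection, TM3-TM6 opening, lipid tilt, an
    eight-variable feature set, time-lagged independent component analysis
    (tICA), and k-means microstate discretization. Synthetic generators for
    fluorescence traces, flux records, and scripted toy trajectories with
    exact ground truth support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    graphics,
    stats,
    utils,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
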