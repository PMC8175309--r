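Package: kpuuCNS
Title: Translational CNS Steady-State Disposition Model for Unbound
    Brain and CSF Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the unbound brain-to-plasma (Kp,uu,brain) and
    CSF-to-plasma (Kp,uu,CSF) steady-state concentration ratios of small
    molecules in rats, monkeys, and humans from molecular weight, logD,
    and in vitro MDR1/BCRP efflux ratios measured in transfected MDCK
    monolayers.  A three-compartment steady-state mass balance (plasma,
    brain extracellular fluid, CSF) connected by passive
    permeability-surface area clearances, transporter-mediated efflux,
    and CSF bulk flow yields closed-form expressions for both ratios.
    Species scaling factors (relative activity factors alpha and beta for
    MDR1 and BCRP, and the structural permeability ratios gamma and
    sigma) are estimated by simultaneous log-space least squares against
    observed Kp,uu values, with relative expression factor (REF)
    alternatives calibrated from cross-laboratory efflux-ratio
    regressions.  Includes derivation of model inputs from raw transport
    and equilibrium-dialysis measurements, prediction-accuracy statistics
    (AFE, AAFE, RMSE, 3-fold bins, paired tests), and a synthetic
    compound-set generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
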