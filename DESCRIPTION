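Package: sanephys
Title: Sinoatrial Node Electrophysiology and Cardiac Biosignal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for murine sinoatrial node (SAN)
    electrophysiology: Boltzmann fits of steady-state HCN channel activation
    and exponential fits of activation/deactivation kinetics, action-potential
    detection with firing/nonfiring mode segmentation of pacemaker recordings,
    time- and frequency-domain heart-rate-variability analysis of RR series,
    baroreflex sequence analysis of beat-aligned blood-pressure/RR data,
    programmed-stimulation conduction measures (SNRT, SACT, ERP, FRP), and
    optical activation mapping of fluorescence frame stacks. Ships seeded
    synthetic-data generators that emulate each recording modality so every
    stage of the pipeline is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
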