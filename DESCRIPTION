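Package: curtaintrack
Title: Single-Molecule DNA-Curtain Tracking and Resection Kinetics
Version: 0.1.0
Authors@R: person("Curtain", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule DNA-curtain imaging
    experiments. Generates ground-truthed synthetic two-channel image stacks
    of quantum-dot-labeled motor proteins translocating on flow-stretched
    48.5 kb DNA tethers (blinking emitters, stage drift, EMCCD noise,
    flow-stop recoil), then recovers their behavior through a full pipeline:
    subpixel 2D-Gaussian point-spread-function localization, fiducial drift
    correction, trajectory linking across blinking gaps, base-pair
    calibration, velocity and processivity estimation, pause detection,
    single-exponential survival fitting, and condition-level statistics
    (initiation and colocalization fractions with bootstrap standard
    deviations, Welch t tests, fold changes, GC-content association).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    survival,
    Biostrings,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
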