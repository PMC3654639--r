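Package: bidecg
Title: Simplified Whole-Heart Bidomain Simulation and 12-Lead ECG Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A computationally light three-dimensional bidomain model of
    torso-embedded whole-heart electrical activity. Modified FitzHugh-Nagumo
    membrane kinetics with seven heterogeneous heart regions (sinoatrial node,
    atria, atrioventricular node, His bundle, bundle branches, Purkinje layer,
    ventricular myocardium) are coupled to a passive torso/lung/blood volume
    conductor on a regular voxel grid. Surface electrode potentials yield the
    standard 12-lead electrocardiogram, Frank-lead orthogonal X/Y/Z channels
    and the vectorcardiogram, together with RMS and signal-averaged ECG
    curves. Tools are included for myocardial-infarction lesion experiments,
    ECG fiducial detection and ST-segment quantification, conduction-velocity
    measurement, configuration handling and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
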