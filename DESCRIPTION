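Package: thalabeta
Title: Amyloid-Coupled Thalamocortical Neural-Mass Model of Alpha-Rhythm
    Slowing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a three-population thalamocortical neural-mass model
    (retina, thalamic relay nucleus, thalamic reticular nucleus) in which the
    inhibitory synaptic time constant is driven by a calibrated sigmoid
    mapping of the amyloid-beta load (PET SUVR). Provides a fixed-step
    stochastic Runge-Kutta integrator with Gaussian white-noise sensory
    drive, an EEG-style spectral chain (zero-phase Butterworth band-pass and
    Welch power spectral density), alpha-band summaries (peak power, dominant
    frequency, 1-Hz sub-band powers), and parameter-sweep drivers for amyloid
    load, thalamic connectivity and sensory drive, reproducing the
    alpha-rhythm slowing associated with Alzheimer's disease.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
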