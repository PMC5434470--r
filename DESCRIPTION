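Package: egmsim
Title: Forward Simulation of Intracardiac Electrograms from an Ablation
    Catheter with Mini Electrodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxel-based forward model of intracardiac electrograms
    recorded by a nonirrigated radiofrequency ablation catheter with
    three embedded mini electrodes.  Simulates action-potential
    propagation in an isotropic myocardial slab (ten Tusscher-Panfilov
    ventricular membrane model, monodomain reaction-diffusion), solves
    the quasi-static extracellular potential over tissue, blood pool and
    catheter, and extracts unipolar and bipolar electrogram features
    (peak-to-peak voltage, peak amplitudes, local activation time).
    Ships the mapping scenarios used to study lesion assessment with
    mini electrodes: catheter tilt, rotation, penetration depth,
    point lesions with and without a thermal border zone, and linear
    lesions with a conduction gap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    knitr,
    Matrix,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
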