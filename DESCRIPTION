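Package: dualmar
Title: Dual-Energy kV/MV Metal Artifact Reduction for CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Sinogram-domain metal artifact reduction for kilovoltage CT
    slices using a co-registered megavoltage cone-beam CT slice of the same
    anatomy. A prior image is built by weighted fusion of the two modalities
    (a relative-deviation weight and a Gaussian distance-to-metal weight),
    forward projected, and used to replace the metal trace of the kV
    sinogram with boundary-continuous surrogate data before filtered back
    projection. Includes a synthetic parallel-beam CT scanner simulator with
    polychromatic beam hardening, Poisson noise and photon starvation;
    piecewise-linear HU calibration and rigid registration of MV onto kV
    grids; the LIMAR, NMAR and NMAR-MV baselines; and evaluation utilities
    (percentage-difference maps, line profiles, region metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
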