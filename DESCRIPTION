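Package: bstdmar
Title: Projection-Domain Bone- and Soft-Tissue Decomposition for Metal
    Artifact Reduction in X-Ray Microtomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reduces metal-induced beam-hardening artifacts in cone-beam and
    parallel-beam microtomography by decomposing each raw projection into a
    soft-tissue transmittance image and a hard-tissue (dense object) image
    before reconstruction. The masked dense region of every projection is
    filled with a smooth membrane interpolant of its boundary values, computed
    either exactly by inverse-distance (Shepard, d^-3) weighting or in linear
    time by convolution pyramids with small fitted kernels. Includes
    filtered-backprojection (parallel 2D) and FDK (circular cone-beam)
    reconstructors with Hamming-windowed ramp filtering, reference
    sinogram-inpainting baselines (LI-MAR and NMAR), a polychromatic
    Beer-Lambert phantom simulator with paired with/without-metal
    acquisitions, and SSIM/PSNR evaluation tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
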