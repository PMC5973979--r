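Package: pclesr
Title: Fibre-Bundle Simulation and Super-Resolution for Confocal Laser Endomicroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probe-based confocal laser endomicroscopy (pCLE) image
    simulation and single-image super-resolution. Provides a physically
    inspired fibre-bundle forward model (irregular fibre lattices, Voronoi
    signal pooling, multiplicative/additive Gaussian noise, Delaunay
    piecewise-linear reconstruction) that turns high-resolution frames into
    perfectly aligned low-resolution counterparts; a phantom generator and
    dataset builder with the matching preprocessing and 64x64 patch
    protocol; reference and reference-free image-quality metrics (SSIM,
    global contrast factor, composite scores, paired t-tests); and a
    desk-scale training harness for small fully-convolutional enhancement
    networks (FSRCNN-like and EDSR-like) with L1 and SSIM+L1 losses, plus
    unsharp-mask and Wiener-deconvolution baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
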