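Package: mitogranule
Title: Semi-Supervised Segmentation and Quantification of Mitochondrial
    Granules in Cryo-Electron Tomograms
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for measuring dense mitochondrial
    matrix granules in cryo-electron tomography (cryoET) volumes. Provides
    a synthetic tomogram generator with voxel-accurate ground truth
    (tubular double-membrane mitochondria, cristae lamellae, lognormally
    sized granules, missing-wedge-like z blurring), the standard tomogram
    post-processing chain (binning, Fourier low/high-pass filtering,
    normalization and sigma clipping, contrast reversal), a two-stage
    semi-supervised volumetric segmentation method (a compact 3D U-Net
    trained on sparsely annotated z slices, then retrained after
    confidence-based pseudo-labeling), connected-component morphometry
    with physical-volume scaling and granule-in-mitochondrion retention,
    and rank-based multi-group statistics (Kruskal-Wallis omnibus with
    Dunn's post hoc over a declared comparison family). Volumes are read
    and written as MRC2014.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
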