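Package: parapet
Title: Voxel-Level FDG Kinetic Parametric Imaging from Late Dynamic PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates net influx rate (Ki) and blood distribution volume
    (Vp) images from a short late dynamic FDG PET acquisition by Monte-Carlo
    propagation of a voxel-level measurement-error model through constrained
    Patlak-type least squares. Includes the Patlak linear reference, the
    Hunter single-time bound and a lesion-level Monte-Carlo comparator, an
    image-derived input function extracted from aorta regions, an
    overlapping-window rebinning scheme producing per-frame mean and
    variance images, mutual-information rigid realignment of the frame
    series, a synthetic dynamic-PET phantom generator with voxelwise ground
    truth, and method-agreement statistics (Bland-Altman ratios, intraclass
    correlation, Wilcoxon paired tests, Monte-Carlo convergence analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
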