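Package: cnscoreg
Title: Multimodal 3D Co-Registration of Central Nervous System Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for placing paired three-dimensional acquisitions of the
    same central nervous system sample -- a low-resolution diffusion-MRI
    derived scalar map and a high-resolution phase-contrast tomogram -- into
    a common reference frame. Provides threshold-and-morphology brain
    masking, anti-aliased and nearest-neighbour resolution matching, spinal
    cord centerline extraction by 3D hysteresis edge detection with
    slice-wise centroids or seeded region growing, centerline straightening
    with rotation-minimizing frames, landmark initialization, Mattes mutual
    information affine registration, a diffeomorphic demons-style
    refinement, and end-to-end brain and cord pipelines. A synthetic phantom
    generator with exported ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
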