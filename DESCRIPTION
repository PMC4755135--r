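Package: pagseg
Title: Connectivity-Based Segmentation of Periaqueductal-Gray-Like Seed Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic streamline tractography on voxelwise fiber-orientation
    fields, cross-correlation k-means clustering of seed-voxel connectivity
    profiles, silhouette-based voxel filtering, per-column connectivity
    profiling with permutation-based column comparisons, winner-take-all
    back-projection, and template-space group probability mapping. Includes a
    synthetic brainstem phantom generator with four ground-truth longitudinal
    columns flanking an aqueduct void, used to validate the full pipeline
    against known column labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, mclust
Config/testthat/edition: 3
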