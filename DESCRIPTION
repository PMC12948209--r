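Package: vox3dmsi
Title: Voxel-Based 3D Reconstruction and Analysis of Serial-Section
    Mass Spectrometry Imaging Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning serial-section MALDI mass spectrometry
    imaging (MSI) data of micron-scale 3D cell cultures (spheroids,
    organoids) into registered voxel volumes and for analysing the
    resulting 3D objects statistically. Reads and writes centroid imzML,
    rigidly registers consecutive sections on a landmark ion image with
    a multi-resolution normalized cross-correlation optimizer, assembles
    multichannel feature volumes with NRRD export, segments voxels by
    bisecting k-means with correlation distance, extracts 3D connected
    voxel objects with size classification and surface/volume geometry,
    and compares object groups by Cohen's d effect sizes and
    Welch t-tests with Benjamini-Hochberg correction (volcano tables).
    Includes a synthetic phantom generator with full ground truth
    (transforms, region labels, object sizes, planted fold changes) so
    every stage of the pipeline can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
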