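Package: trabmorph
Title: Trabecular Bone Morphometry from Micro-CT and Dental CBCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring trabecular bone microarchitecture (BV/TV, TbTh,
    TbN, TbSp) from 3D grayscale volumes, with a cumulative image-preprocessing
    ladder for dental cone-beam CT (sharpening, despeckling, per-slice isodata
    thresholding, and density-calibrated air-voxel removal), exact
    maximal-inscribed-sphere local thickness with a brute-force oracle, a
    synthetic cancellous-bone phantom generator with known ground truth and a
    phenomenological CBCT degradation model, minimal TIFF-stack and DICOM-series
    readers, and a cohort experiment runner producing per-group summaries,
    paired t-tests, and Pearson correlations against the micro-CT reference.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
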