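Package: adaptdose
Title: Dose Prediction for Online Adaptive Radiotherapy with Plan-Conditioned 3D U-Nets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts voxel-wise dose distributions for adaptive radiotherapy
    sessions from anatomy and pre-treatment plan information. Implements a
    baseline single-head 3D U-Net and a dual-head variant (MHU-Net) whose
    secondary encoder ingests the pre-treatment plan (contours, distance maps
    and the approved dose) so that per-patient organ-sparing intent conditions
    the adaptive prediction. Includes session I/O with NIfTI volumes,
    resampling, channel assembly with exact Euclidean distance maps,
    patch-based training with geometric augmentation, dose-volume histogram
    and Dx% dosimetry with paired Wilcoxon model comparison, and a synthetic
    phantom simulator that generates paired pre-treatment/adaptive plans with
    persistent sparing intent for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
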