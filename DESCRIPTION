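Package: dreho
Title: Dynamic Regional Homogeneity Mapping and Group Inference for
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes regional homogeneity (Kendall's coefficient of
    concordance over voxel neighborhoods) and its sliding-window temporal
    variability (dynamic ReHo) from 4D resting-state fMRI volumes, with
    temporal preprocessing (volume discard, detrending, band-pass
    filtering, head-motion screening), covariate-adjusted voxelwise group
    inference with Gaussian-random-field cluster correction, clinical
    association analyses, and leave-one-out cross-validated linear
    support-vector-machine classification on cluster-mean features. A
    seeded synthetic-cohort generator produces two-group studies with
    known injected coherence dynamics so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
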