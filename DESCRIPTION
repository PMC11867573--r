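Package: contourvar
Title: Contour Variability Analysis for Radiotherapy Organ-at-Risk Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies agreement between 3D organ-at-risk delineations in
    radiotherapy imaging studies. Implements the Dice similarity coefficient,
    directed, undirected and percentile Hausdorff distances (including the
    symmetrized 95th-percentile Hausdorff distance), intraclass correlation
    ICC(2,1) for volume consistency, and Wilcoxon rank-sum comparisons, and
    orchestrates three study designs over a cohort of co-registered binary
    label volumes: interobserver, intersequence and automatic-versus-manual
    variability. Ships a deterministic synthetic pelvic-phantom cohort
    generator with controllable boundary perturbations so the whole pipeline
    can be exercised and validated without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
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
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
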