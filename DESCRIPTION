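Package: dosewarp
Title: 4D Deformable Dose Accumulation for Respiratory-Phase Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quasi-4D evaluation of radiotherapy plans in moving anatomy.
    Provides a deformable digital respiratory liver phantom with analytic,
    invertible ground-truth displacement fields; multi-resolution optical-flow
    (Horn-Schunck) deformable image registration; displacement-vector-field
    dose warping with equal-weighted path-integrated accumulation over
    respiratory phases (including reduced phase subsets); and dose-volume
    histogram plan-quality metrics (Dx, homogeneity index D2/D98,
    DVH-based biologically effective dose) for comparing conventional static
    3D dose calculations against 4D accumulated dose. Reads and writes NRRD
    and MetaImage scalar volumes, masks, and vector fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
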