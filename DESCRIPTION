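Package: fedspine
Title: Federated Learning Simulation for Lumbopelvic Landmark Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cross-silo federated learning for anatomical landmark
    localization on sagittal spine radiographs. Provides a synthetic
    multi-hospital cohort generator with exact ground-truth landmarks and
    lumbopelvic angles (sacral slope, pelvic incidence, pelvic tilt, lumbar
    lordosis), a stacked-hourglass convolutional localizer with a
    differentiable spatial-to-numerical (DSNT) coordinate head trained with a
    Euclidean-plus-divergence loss, three federated aggregation strategies
    (FedAvg, FedOpt, FedProx) alongside centralized and per-hospital local
    baselines, and an evaluation suite covering per-vertebra localization
    error, per-angle absolute error, internal/external cross-site testing and
    percentage-of-correct-predictions curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
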