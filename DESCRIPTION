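Package: srsrescan
Title: Feasibility Analysis for Reusing Initial SRS Planning CTs at Repeat Treatments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative quality-assurance pipeline for assessing whether an
    initial stereotactic-radiosurgery (SRS) planning CT can stand in for a
    repeat CT: rigid 6-DOF mutual-information registration with a
    residual-displacement chain, 16-direction target-to-skull ray tracing with
    gradient-based edge detection, image-similarity scoring (normalized mutual
    information and Pearson correlation), and 3D gamma-index dose comparison
    (1 mm / 1% global criteria with a 10% low-dose threshold). Ships a digital
    head-phantom generator (repeat CTs under known rigid motion, T1-like MRs,
    analytic SRS dose distributions) so the whole pipeline runs end-to-end
    with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
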