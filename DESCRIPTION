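Package: fracverify
Title: ROI-Level Adjudication of Fracture Detector Proposals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Second-stage verification of high-recall fracture-detector
    proposals on radiographs. Candidate regions of interest (ROIs) are
    re-scored by a compact convolutional adjudicator conditioned on the
    detector confidence, trained with focal loss and iterative hard-negative
    mining, and final decisions are taken on a convex fusion of adjudicator
    and detector scores with a validation-selected operating threshold.
    Includes a seeded synthetic radiograph benchmark (bright bone bands,
    thin fracture-like discontinuities, growth-plate and overlapping-edge
    confounders) with a parametric mock detector, patient-disjoint
    splitting, calibration diagnostics (reliability bins, expected
    calibration error, Brier score), bootstrap confidence intervals,
    Wilcoxon paired comparisons, detection metrics (IoU, NMS, average
    precision, mAP at an IoU threshold), and Grad-CAM saliency with
    pointing-game and overlap-based localization scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
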