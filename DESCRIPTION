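Package: vesselrank
Title: Subjective Assessment and Ranking of Retinal Vessel Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-stage subjective-assessment studies of retinal
    vessel segmentation methods. Thresholds probability maps into binary
    segmentation masks and computes full-reference per-pixel objective
    metrics (accuracy, sensitivity, specificity, precision, F1, Matthews
    correlation); builds diagnosis and pairwise-comparison surveys with
    embedded intra-observer control questions; scores diagnosis responses
    with a certainty-weighted grading score and aggregates pairwise
    preferences into Copeland rankings; quantifies reliability via
    Cronbach's alpha and Guttman's lambda-6 with Feldt, asymptotic and
    bootstrap confidence intervals, and inter-rater agreement via Fleiss'
    kappa for m raters; compares dependent grade samples with Yuen's
    trimmed-means test and the Algina-Keselman-Penfield robust effect
    size. A synthetic-data module simulates branching vessel masks,
    degraded probability maps, and observer response panels with known
    latent structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
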