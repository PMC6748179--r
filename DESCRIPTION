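Package: iseval
Title: Usability Evaluation of Interactive Image Segmentation Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Benchmarks interactive image segmentation front-ends without a
    human in the loop. Provides a GrowCut cellular-automaton segmentation
    engine extended with a per-pixel label-change counter, seed-point
    suggestion from influence maps, headless simulators of three user
    interface paradigms (semi-manual scribbling, guided four-option choice,
    and joint seed toggling) driven by rule-based robot users, scoring of the
    System Usability Scale (SUS) and AttrakDiff-2 questionnaires, and a
    feature-extraction plus gradient-boosted-regression pipeline that
    predicts questionnaire scores from interaction logs alone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
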