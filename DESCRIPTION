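Package: marblesense
Title: Detection of Artificially Marbled Beef from Smartphone Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Image-analysis pipeline for screening retail beef photographs for
    artificial marbling (fat injection). Applies an elliptical region-of-interest
    mask to 960x720 RGB captures, partitions the region into square grid blocks,
    extracts uniform local binary pattern (LBP) texture histograms together with
    per-block colour statistics in RGB, HSV and CIE L*a*b* space, classifies each
    block with a radial-basis-function support vector machine, and aggregates
    block labels to an image-level verdict by priority-tie-break majority voting.
    Includes block-level and image-level evaluation metrics (misjudgment rate,
    detection rate, precision, classification rate, F1), a seeded synthetic
    marbling image generator emulating Wagyu, regular and fat-injected surface
    phenotypes, and capture-condition perturbations (brightness ladder, label and
    reflection occlusion, camera tilt) for robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
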