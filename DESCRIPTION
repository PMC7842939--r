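Package: bedrestdt
Title: Bedrest and Wake Detection from Waist-Worn Accelerometer Epoch Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying bedrest (nighttime sleep plus daytime naps)
    and wake periods in minute-epoch triaxial accelerometer recordings from
    preschool children. Implements a four-step decision-tree detector driven by
    block averages and start/end count triggers, an automated version of the
    visual-scoring heuristic used as a reference, Choi-style non-wear
    detection, recording-validity quality control, a Sadeh sleep-scoring
    comparator, epoch- and interval-level agreement statistics (sensitivity,
    specificity, accuracy, weighted Cohen's kappa, overlap coefficient), a
    Nelder-Mead simplex optimizer for the detector parameters, and a seeded
    synthetic actigraphy generator with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
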