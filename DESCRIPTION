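Package: larvatrack
Title: High-Throughput Tracking and Behavioral Classification of Zebrafish
    Larvae from High-Speed Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks multiple zebrafish larvae in circular wells from
    high-speed grayscale video, extracts the tail midline and the signed
    tail-bending angle per frame, segments swim bouts from the bend-angle
    trace, computes per-bout global kinematic parameters and tail-curvature
    kymographs, classifies maneuvers (slow forward swim, routine turn,
    escape) with a two-stage PCA plus linear-SVM classifier, and quantifies
    the recurrence of maneuvers within and between larvae with a
    Markov-chain transition index over time and distance windows, including
    a permutation test. A synthetic-video generator with exact ground truth
    (core positions, midlines, bend angles, event boundaries, class labels)
    supports validation of every stage without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    yaml,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
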