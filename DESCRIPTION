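Package: larvatrack
Title: Quantifying Insect Larval Locomotion from Time-Lapse Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for high-resolution analysis of single-larva locomotion in
    circular arenas from time-lapse image sequences. Implements
    average-intensity background modelling, subtraction, binarization and
    centre-of-mass particle detection; trajectory quality control
    (out-of-arena filtering, multi-detection averaging, carry-forward gap
    filling); movement/stationary scoring at a displacement threshold,
    30-second-window segmentation of continuous locomotion bouts, and
    per-larva locomotion metrics (total distance, median moving speed, median
    bout duration, bout frequency); time-segmented spatial occupancy
    summaries; and exact Wilcoxon-Mann-Whitney rank-sum comparison of two
    groups. Includes a two-state correlated-random-walk larva simulator and
    frame renderer that produce ground-truthed synthetic recordings for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
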