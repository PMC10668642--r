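Package: flocktrack
Title: Multi-Object Tracking and Activity Quantification for Group-Housed Poultry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the activity of group-housed animals from
    top-down video detections. Implements a tracking-by-detection engine with a
    two-tier confidence-cascade association (high-confidence detections matched
    first, low-confidence detections recovered in a second pass) over a Kalman
    constant-velocity motion model; image-moment centroid extraction from binary
    instance masks; the single-frame average displacement (SFAD) activity
    statistic with its trajectory-validity filters and group/age-stage
    aggregation; CLEAR-style multi-object tracking accuracy (MOTA) evaluation;
    and a synthetic top-down cage-scene simulator (correlated random walks,
    elliptical body masks, detector noise) so the whole pipeline can be
    exercised and validated without real video or a trained detector. Reads and
    writes MOTChallenge-format text files and PNG mask rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
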