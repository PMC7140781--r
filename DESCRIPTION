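Package: skelgaze
Title: Skeleton-Based Analysis of Gaze on Animated Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps eye-tracking samples recorded while viewers watch animated
    characters onto dynamic body-part areas of interest defined by an
    articulated skeleton. Detects fixations with the dispersion-threshold
    (I-DT) algorithm, accumulates per-joint fixation time, colors a skinned
    character mesh as a heat mesh via linear-blend skinning weights, builds
    single and aggregated viewer timelines with synchronization (overlap)
    statistics, and temporally aligns semantically equivalent motion
    sequences with dynamic time warping on a quaternion geodesic posture
    distance. Includes readers and writers for a documented XML experiment
    dialect, keyframe and motion text formats, OBJ meshes with skinning
    weight sidecars, and a synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    ggplot2,
    xml2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
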