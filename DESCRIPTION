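Package: fogtrack
Title: Indoor Position and Orientation Tracking for Freezing-of-Gait Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plan-view depth-camera person tracking fused with smartphone
    inertial orientation estimation for monitoring Parkinson disease patients
    with Freezing of Gait. Implements a particle-filter tracker over plan-view
    height/occupancy maps built from depth images, gravity-referenced (GROE)
    and magnetic-plus-gravity (AOE) gradient-descent quaternion orientation
    filters, a feed-forward height-template heading classifier, two
    vision-inertial heading fusion methods, a seeded synthetic sensor-data
    generator replicating the laboratory accuracy-assessment protocol, and the
    stop-window evaluation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    EBImage
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
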