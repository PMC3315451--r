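Package: flockfit
Title: Data-Driven Models of Collective Motion from Trajectory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring interaction rules in moving animal groups
    directly from multi-agent trajectory data. Simulates topological
    (k-nearest-neighbour) Vicsek flocks and goal-directed zonal flights,
    builds neighbour-aware embeddings of trajectories, fits radial basis
    function dynamical models with description-length-controlled complexity,
    runs free multi-agent rollouts of the fitted models, and extracts
    collective-behaviour signatures such as flock separation dynamics,
    alignment rules and attraction-repulsion curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
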