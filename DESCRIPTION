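Package: tiltfall
Title: Geometry-Based Models of Falling-Direction Judgments for Tilted Objects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how the falling direction of a tilted
    object can be judged from object geometry alone. Provides analytic
    rigid-body statics for frustum-of-revolution stimuli (centroids,
    critical tipping angles, ground-truth fall labels), experiment
    designs and trial grids, a simple scene rasterizer, simulated
    logistic observers with a configurable safe-side bias, psychometric
    function fitting with bootstrap point-of-subjective-equality (PSE)
    estimates, leave-one-object-out linear max-margin classifier models
    trained on geometric features or image embeddings, and the
    comparison statistics used to relate human and model judgments
    (trend analyses, variance partitioning, permutation tests, and
    weighted principal-component correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    withr,
    jsonlite,
    yaml,
    MASS
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
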