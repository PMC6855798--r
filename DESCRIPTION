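Package: taskconn
Title: Task-Dependent fMRI Connectivity Analysis with Permutation Cluster
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing task-dependent functional-connectivity
    changes in a two-group, two-condition (stimulation versus sham),
    two-task (memory retrieval versus rest) crossover design.  Implements
    ROI-sphere extraction and Fisher-z network interconnectivity, linear
    mixed-effects contrasts with a tSNR covariate and FDR-corrected
    edge-level tests, whole-brain global connectedness maps with a
    label-flipping permutation cluster-extent null, seed-based driver maps
    and network-allegiance classification, memory-task scoring, and robust
    brain-behaviour regression.  A synthetic-data generator with planted
    connectivity and behavioural effects makes every stage testable
    without access to raw scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    MASS,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
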