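Package: BottleneckProfiler
Title: Identifying Bottlenecks for the Implementation of Health Promotion Interventions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for screening survey data on conditions for the implementation of
    health promotion interventions. Implementers rate the presence of 47 conditions
    (seven categories, five-point Likert items) and select a top-5 of importance for
    each implemented intervention. The package dichotomizes presence ratings into
    optimal versus sub-optimal, marks top-5 conditions as important, flags conditions
    that are both sub-optimal and important as bottlenecks, stratifies bottleneck
    rates by frequent intervention system (behaviour change method x health theme x
    implementation setting) and by each system characteristic, and labels every
    (frequent system, condition) pair as an expectedly present, unexpectedly present,
    or unexpectedly absent bottleneck. A synthetic cohort generator with injected
    condition-by-characteristic effects supports calibration and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epidemiology, Survey, Classification
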