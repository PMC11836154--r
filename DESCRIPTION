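Package: hipfracsim
Title: In Silico Clinical Trials of Hip Fracture Incidence in Virtual Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator for in silico clinical trials of hip
    fracture in postmenopausal women. Builds a principal-component
    statistical atlas of femur geometry and density features, samples
    virtual cohorts whose areal bone mineral density distribution matches
    a clinical target, models falls as a homogeneous Poisson process,
    converts each fall into a soft-tissue-attenuated peak impact force on
    the greater trochanter, evaluates direction-dependent femur failure
    loads (exact strain-criterion evaluator on supplied strain fields, or
    a fast calibrated surrogate), and predicts multi-year fracture
    incidence with an absorbing Markov-chain follow-up, bootstrap
    convergence diagnostics, and cohort-equivalence tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
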