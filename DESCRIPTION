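Package: primekin
Title: Calcium-Dependent Vesicle Priming and Exocytosis Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits a sequential-pool kinetic model of
    Ca2+-dependent large dense-core vesicle priming and fusion in
    neuroendocrine (chromaffin) cells.  Provides the priming-sensor
    Ca2+-binding kinetics, steady-state initialization and capacitance-trace
    simulation of the model; Hill-affinity estimation from flash-photolysis
    release fractions; weighted simultaneous multi-condition model fitting;
    exponential burst decomposition and window-based pool readouts of
    capacitance traces; amperometric spike and foot analysis with per-cell
    median summaries; docked-pool morphometry from electron-microscopy
    measurements; and seeded synthetic-data generators for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
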