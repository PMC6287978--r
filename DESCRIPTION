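Package: mitoswitch
Title: Two Interlinked Bistable Switches of Mammalian Mitotic Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action ordinary differential equation model of the mitotic
    entry/exit decision in mammalian cells, built from two interlinked bistable
    feedback loops: Cdk1:CycB auto-activation through Wee1/Cdc25 and PP2A:B55
    inactivation through the Greatwall-ENSA pathway. Provides stiff simulation
    of in-silico inhibitor protocols on analog-sensitive Cdk1 cells,
    steady-state and saddle-node (fold) analysis of substrate phosphorylation
    versus inhibitor dose, population-level dose-response curves and IC50s
    under log-normal cell-to-cell cyclin B variability, a two-stage fit of the
    cyclin B distribution to endpoint assay data, and a synthetic generator for
    the endpoint hysteresis assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
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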