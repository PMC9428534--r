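Package: batchspawner
Title: Eco-Evolutionary Simulation of Batch-Spawning Fish Under
    Size-Selective Fishing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Individual-based eco-evolutionary simulation of an Atlantic
    cod-like population in which asymptotic body length is a heritable,
    evolving quantitative trait. Mature fish spawn either as
    multiple-batch spawners (eggs spread over many within-season batches,
    a risk-spreading strategy with per-batch survival costs) or as
    single-batch spawners (all eggs in one event). Whole egg batches
    survive or die through environmentally forced Bernoulli trials, and
    populations are exposed to size-selective trawl harvest with a
    biomass-triggered moratorium. The package provides the annual-cycle
    engine, a full-factorial scenario runner with reproducible seed
    streams, and summary statistics including geometric-mean
    across-generational fitness, realized individual fitness, failed
    spawning proportions, fishing-period lengths and population age
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
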