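Package: traycycle
Title: Closed-Loop Simulation and Base-Stock Sizing of Surgical Tray Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discrete-event simulation of the closed-loop cycle of reusable
    surgical instrument trays through a hospital Central Sterilisation
    Services department (pre-cleaning, disinfection, assembly, wrapping,
    steam sterilisation, sterile storage), driven by a stochastic surgery
    schedule generator with Poisson surgery counts, lognormal durations and
    worst-fit operating-room packing. Includes three tray base-stock sizing
    heuristics (empirical weekday-quantile base stock, a cycle-time rule,
    and a discrete-time Markov-chain service-level method), plus the
    simulation output-analysis machinery needed to compare them: MSER-m
    warm-up truncation, replication confidence intervals, and a common
    random numbers policy-comparison driver. A synthetic-instance generator
    emulates the demand structure of a mid-size hospital so every component
    is testable without confidential hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
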