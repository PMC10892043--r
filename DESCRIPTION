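Package: adlgraph
Title: Knowledge-Graph Detection of Problems in Activities of Daily Living
    from Smart-Home Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts raw smart-home sensor streams (boolean state-change
    signals from motion/door/panic sensors and wattage series from wall
    plugs) into sensor events, composes events into activities of daily
    living (ADLs) via protocol templates, represents devices, observations,
    activities and participants as an RDF knowledge graph under an
    SSN/SOSA-aligned ontology, and detects execution problems (too long
    duration, divergence from protocol, extra steps, missing steps) with
    four declarative graph-pattern rules. Includes a seeded synthetic
    cohort simulator (healthy controls, subjective cognitive decline, mild
    cognitive impairment) calibrated to published group-level activity
    statistics, and per-group reporting of detected problems.
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
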