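Package: trajmine
Title: Temporal Disease Trajectory Mining from Longitudinal Diagnosis Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines statistically significant, directional diagnosis pairs from
    longitudinal ICD-10 diagnosis registries using matched-control relative
    risk estimation and exact binomial tests, concatenates the pairs into
    linear disease trajectories followed by a minimum number of patients, and
    merges trajectories into directed disease trajectory networks with
    privacy-aware export to Cytoscape JSON and delimited tables. Includes a
    synthetic registry simulator with planted directional progression effects
    so every statistical property of the pipeline can be tested without
    access to person-sensitive registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
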