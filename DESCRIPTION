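Package: specshift
Title: Change Classification and Conservation-Assessment Impacts for Curated Specimen Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare two snapshots of a curated herbarium specimen
    database, classify every record-level difference (additions, nomenclatural
    changes, taxonomic lumping and splitting, corrected misidentifications,
    rank changes, and georeferencing changes), compute extent of occurrence
    (EOO) as a minimum convex polygon area and assign preliminary IUCN
    Criterion B categories per species per snapshot, attribute per-specimen
    hypothetical EOO impacts to each change type via one-change-at-a-time
    counterfactuals, and test category-shift and change-profile differences
    with conjugate Bayesian estimation. A seeded simulator generates paired
    snapshots with a ground-truth change log for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
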