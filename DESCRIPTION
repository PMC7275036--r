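Package: traitsynth
Title: Harmonize and Condense Bacterial and Archaeal Phenotypic Trait Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible, table-driven workflow for merging heterogeneous
    bacterial and archaeal trait sources into harmonized data products. Raw
    per-source tables are standardized against a 23-trait registry (declarative
    preparation specs: column renames, range splitting, unit conversion, taxon
    mapping, referencing), unioned into a sparse record-level table with
    seven-rank lineages under pluggable NCBI- or GTDB-style taxonomies, and
    aggregated to one row per species. Species aggregation uses strict-majority
    consensus for plain categorical traits, a specificity-aware cascade for
    multilevel vocabularies, per-level condensation of hierarchical
    isolation-source labels, and mean/standard deviation/count for numeric
    traits. Curation is transparent: term translation tables, a scripted
    corrections table, deduplicated reference tracking and gap filling from an
    auxiliary table are all plain CSV inputs, and every drop or change is
    logged. A seeded fixture generator produces synthetic sources with known
    ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    yaml,
    jsonlite,
    ggplot2,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
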