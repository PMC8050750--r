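Package: fhirprep
Title: Criteria-Based Filtering of FHIR Resources into Analysis-Ready Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning HL7 FHIR R4 clinical resources (Patient,
    Encounter, Condition, Procedure, Observation, MedicationStatement) into
    flat, analysis-ready feature tables. Resources are held in a single-table
    document store; a JSON filter-specification language expresses a base
    resource selection (by code, value and demographics) together with
    inclusion and exclusion criteria that match either at any time for a
    patient ("ever") or within a day-window of the base resource, with
    encounter periods as a fallback time anchor. A synthetic hospital data
    generator with ground-truth labels makes every stage testable offline,
    and three worked clinical scenarios (indirect reference-interval
    preparation, anemia in cancer, drug adverse effects) exercise the full
    pipeline down to contingency-table statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
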