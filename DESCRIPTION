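Package: sdtm2omop
Title: Transform SDTM-Formatted Registry Data to the OMOP Common Data Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An extract-transform-load toolkit for harmonizing patient-registry
    data captured in the CDISC Study Data Tabulation Model (SDTM) into the
    OMOP Common Data Model (CDM) v5.3.1. Implements sample selection with a
    full exclusion ledger, deterministic imputation of partial and missing
    dates (free-text extraction, timepoint anchors, previous drug interval,
    reference-timepoint comparison, and a source-hierarchy rule for death
    dates), source-to-standard concept resolution with custom-vocabulary
    extension and CONCEPT_ANCESTOR transitive-closure maintenance, domain
    routing with FACT_RELATIONSHIP construction, mapping quality-assessment
    accounting, and a deterministic synthetic-registry generator for
    validating every stage against a ground-truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
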