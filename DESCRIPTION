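Package: metasheet
Title: Structured Experiment Metadata Along the Data-Lifecycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parse, validate, generate and export structured experiment
    metadata sheets that follow the biomedical data-lifecycle (Planning,
    Conduction, Measurement-Matching). Provides a typed model of the sheet
    and its controlled-vocabulary and dependent-field resources, a
    spreadsheet reader/writer for the workbook layout, a validation engine
    with located issues, factorial final-group expansion, ID-table
    generation with up to two levels of sample partitioning, measurement
    data-file linkage resolution, exporters to NCBI GEO metadata
    spreadsheets, OWL/XML and RDF/XML ontology individuals, and a
    language-neutral experiment bundle loadable as a SummarizedExperiment.
    Includes a deterministic fixture generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    readxl,
    zip,
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    SummarizedExperiment,
    S4Vectors,
    withr,
    digest
Config/testthat/edition: 3
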