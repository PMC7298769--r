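Package: shepherd
Title: Resumable Workflow Execution with Versioned Tool Modules and
    Provenance Logging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless workflow-management engine for bioinformatics
    pipelines. Workflows are XML documents composed of reusable, versioned
    tool modules; tasks are multiplied over samples via process blocks and
    scheduled across local and cluster-style (spool) executors. Every
    (sub)task success is appended to a crash-safe provenance log together
    with its resolved parameters, return values, and module and third-party
    software versions. The log drives incremental re-execution (resume
    mode, keyed on parameter-combination fingerprints), detach/reattach of
    the scheduler while cluster jobs keep running, automatic generation of
    a step-by-step methods report, and a static searchable reference book
    of module documentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
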