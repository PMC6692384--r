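Package: custodian
Title: Data Custodianship for Translational Research Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A desk-scale data-custodianship environment for translational
    medicine studies.  Provides an ISO/IEC 11179-style data-element
    registry, a four-layer dataset meta-model with shipped CDISC
    SDTM-dialect and ISA-style templates, a project/study/activity domain
    graph, descriptor-driven validation and atomic loading of delimited
    data files into a primary-dataset repository, integration of dataset
    content into a common-observation-model warehouse with cross-study
    feature harmonisation, a faceted cohort query engine whose checkout
    produces query-storing analysis datasets with regenerable exports, and
    a deterministic synthetic multi-study project generator for testing
    the full lifecycle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
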