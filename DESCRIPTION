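Package: chtriage
Title: Clonal Hematopoiesis-Aware Variant Triage for ctDNA Liquid Biopsy
Version: 0.1.0
Authors@R:
    person("JFCR", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Error-corrected variant calling from UMI-tagged ultradeep amplicon
    reads (molecular-family consensus, functional-family and supporting-family
    thresholds), classification of plasma cell-free DNA variants into
    tumor-derived, clonal-hematopoiesis (CH)-related, or unknown origin using
    matched tumor tissue and peripheral-blood-cell (PBC) call sets, cohort
    concordance and detection-rate statistics, and longitudinal post-operative
    monitoring that prevents persistent CH variants from being misread as
    residual disease. Includes a matched three-compartment synthetic cohort
    generator with ground truth so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
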