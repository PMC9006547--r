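Package: tadbench
Title: Evaluation Toolkit for Topologically Associating Domain Callers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality metrics and benchmarking machinery for topologically
    associating domain (TAD) calls on Hi-C/Micro-C contact matrices:
    distance-stratified adjusted-R2 signal partitioning, regulatory-element
    enrichment metrics around boundaries (average peak, boundary tagged
    ratio, fold change, Gaussian p-value ratio, Jaccard variants),
    boundary-level true/false positive rates against planted truth,
    replicate concordance and reproducibility levels, corner-dot (loop
    extrusion) stratification, quartile-based caller ranking, a labeled
    synthetic contact-matrix and peak-track simulator, and a reference
    insulation-score TAD caller.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
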