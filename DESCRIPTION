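Package: genetrust
Title: Content-Addressed Sharing and Completeness Scoring of Deidentified
    Cancer Clinical and Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained framework for assembling, deidentifying and
    sharing per-patient cancer clinical and genomic data bundles.  Provides
    a local content-addressable store keyed by SHA-256 digests of a
    canonical JSON serialization, per-steward append-only submission
    ledgers with a top-level provenance hash anchored to a simulated
    blockchain log, HIPAA-style deidentification transforms (date to
    age-in-days conversion, allow/deny-list filtering, germline variant
    removal, and a PHI leak scanner), readers for OMOP common-data-model
    table extracts, cancer-registry exports, variant report XML and
    somatic VCF, cohort-level somatic variant summaries, and a 0-5
    completeness-scoring rubric comparing registry against OMOP capture
    with a tie-corrected Wilcoxon signed-rank test.  A seeded synthetic
    cohort generator produces identified raw inputs with ground-truth
    sidecars so the whole pipeline is testable without access to any
    real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    jsonlite,
    stats,
    tibble,
    utils,
    vcfR,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
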