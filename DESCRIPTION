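Package: digephen
Title: Case-Finding and Validation Toolkit for Digestive Cancer in
    Primary-Care Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and validates electronic-health-record phenotyping
    algorithms for digestive cancer (esophageal, gastric, pancreatic,
    hepato-biliary, colorectal) in Spanish primary-care databases.
    Combines ICPC-2/ICD-9 diagnostic code lists with lexicon-based
    free-text mining of descriptors and clinical notes, resolves
    co-occurring cancers with a deterministic code hierarchy, stratifies
    potential cases by information completeness, and implements the
    stratified validation workflow: reviewer sampling plans, linearly
    weighted Cohen's kappa, per-stratum and weighted positive predictive
    values with binomial confidence intervals, sensitivity scenarios for
    unsupported cases, and crude plus direct age-sex standardized
    incidence rates. A seeded synthetic-cohort generator with planted
    ground truth makes the whole pipeline testable without access to
    restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
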