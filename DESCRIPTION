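Package: chemtrace
Title: Chemical Knowledge-Base Screening of Untargeted Food Metabolomics Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative annotation triage for untargeted food metabolomics
    feature tables. Structure-annotated compounds are cross-referenced by
    InChIKey against curated pharmaceutical, food-contact-chemical and
    agrochemical references; formula-only features are screened for putative
    xenobiotics by molecular-formula membership in a union of natural-product
    databases, with fluorine prioritization, double-bond-equivalent and
    heteroatom profiling, and Van Krevelen chemical-space coordinates. A
    taxonomy-aware screen flags compound-genus pairs absent from
    natural-product occurrence records, and ontology-aware aggregation
    summarizes signal intensities across food groups. A seed-reproducible
    synthetic study generator with planted ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
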