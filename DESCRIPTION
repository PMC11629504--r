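Package: TrioTriage
Title: Trio Exome and Array-CGH Variant Triage for Essential Autism Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based triage of trio whole-exome sequence variants and
    array-CGH copy-number variants in essential autism spectrum disorder
    cohorts. Implements quality and frequency filtering, trio inheritance
    assignment, compound-heterozygote pairing, a four-criterion
    pathogenicity classifier with SFARI and non-SFARI branches, a
    compound-heterozygosity class combiner, CNV retention and gene-level
    rearrangement typing, per-patient best-finding resolution, and
    cohort-level diagnostic-yield statistics. Ships a deterministic
    synthetic trio-cohort generator with planted ground-truth labels so the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
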