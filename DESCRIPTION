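Package: studlines
Title: Uniparental-Marker Verification of Maternal and Paternal Lines in
    Closed Studbook Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for verifying historical pedigree lineages in closed
    horse studs with uniparental markers. Calls variants in mitochondrial
    D-loop control-region sequences against a fixed reference coordinate
    frame, clusters identical variant profiles into named haplotypes,
    classifies haplotypes into haplogroups with configurable diagnostic
    motif rules, and runs an iterative haplotype-to-family assignment
    (uniqueness, exclusion, majority, tie) with an exhaustive matching
    oracle and retention reporting. Types male-specific Y-chromosome
    haplotypes from three diagnostic loci. Computes probability-of-gene-
    origin pedigree statistics: inbreeding coefficients, founder and
    ancestor counts, equivalent founders, effective ancestors, founder
    genome equivalents by gene dropping, and pedigree completeness.
    Includes a seeded closed-stud simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
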