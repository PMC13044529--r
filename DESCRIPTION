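Package: fsmEdit
Title: Frameshift Neoantigen Calling and Immunoediting Analysis for MSI Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects shared frameshift-mutation (FSM) neoantigens at a catalog of
    coding mononucleotide-repeat loci from per-locus read evidence, scores
    microsatellite instability, applies a tumor-only/tumor-normal somatic variant
    filter cascade, translates deletion frameshifts into frameshift peptides,
    enumerates MHC class I and II candidate epitopes with a pluggable binding
    predictor, and quantifies immune editing (lost/kept/gained neoantigens)
    across sequential tumors of the same patient. Includes a seeded synthetic
    cohort generator with an immunogenicity-dependent retention model for
    testing and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
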