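Package: neoscreen
Title: Functional Neoantigen Screening from Somatic Variants to Pooled
    ELISPOT Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for function-first identification of tumor neoantigens
    recognized by endogenous CD4+ and CD8+ T cells. Implements the
    expression-filter cascade for annotated somatic variants (coding
    consequence, RNA expression evidence, strict VAF and read-count
    thresholds), design of mutant/wild-type long-peptide pairs with the
    mutated residue anchored at configurable positions, minimal-epitope
    tiling, tethered helper-effector constructs, peptide pooling with
    two-stage deconvolution of pooled IFN-gamma ELISPOT screens, a
    four-criterion ELISPOT positivity rule (spot count, Student's t test,
    stimulation index, Poisson background test), rollup of single-peptide
    calls to mutation-level hits with T cell subset attribution, and an
    audit of MHC affinity prediction cutoffs against functionally
    validated epitopes. A seeded synthetic-data generator plants known
    tier memberships and immunogenic peptides so the whole pipeline is
    testable end to end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Immunology, SomaticMutation, Sequencing, Software
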