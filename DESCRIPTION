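Package: mitokin
Title: Whole Mitochondrial Genome Kinship Interpretation for Maternal Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic interpretation of whole mitochondrial genome
    (mtGenome) haplotypes between maternally related individuals. Implements
    EMPOP-style variant-string parsing against a circular reference,
    nomenclature normalization (3' shifting of indels on the light strand,
    C-stretch masking), minor-allele-frequency threshold heteroplasmy calling
    from per-position read counts, maternal pedigree traversal with meiosis
    counting and exhaustive pair enumeration, pairwise comparison under ISFG
    (shared-allele) and strict heteroplasmy-handling rules with SWGDAM
    three-tier outcome classification, Clopper-Pearson and Wilson binomial
    confidence intervals, chi-squared and Fisher exact contingency tests, and
    a multigenerational pedigree + mtDNA transmission + sequencing-depth
    simulator for end-to-end validation without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
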