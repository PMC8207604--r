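Package: fnbfind
Title: Identify Candidate Causative Deletions in Fast-Neutron Mutants from
    Multi-Sample Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forward genetics with fast-neutron bombardment (FNB)
    mutant collections. FNB mutagenesis produces chromosomal deletions from a
    single base pair up to hundreds of kilobases; given joint multi-sample
    variant calls for a mutant pool, a wild-type-like pool, a wild-type
    control and optional cohort lines, the package filters deletions by the
    genotype pattern expected under the experimental design (recessive
    bulked-segregant, non-recessive F3-confirmed, or individual mutant),
    subtracts shared cohort background, classifies each surviving deletion's
    coding consequence against a GFF3 annotation, detects large
    presence-absence deletions from windowed read-depth dropout, and tests
    phenotypic segregation ratios. A self-contained simulator generates
    complete synthetic experiments (genome, annotation, variants, depth
    tracks) with a truth set for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Rsamtools,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
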