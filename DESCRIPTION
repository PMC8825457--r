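Package: sinescout
Title: Structure-Aware Annotation of Short Interspersed Nuclear Elements in Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates short interspersed nuclear elements (SINEs) in plant
    genome assemblies. Candidate elements are discovered de novo from
    structural features (RNA-polymerase-III box A/B promoter motifs, spacing
    constraints, and a low-complexity 3' tail) or imported from precomputed
    profile-HMM homology hit tables. Candidates are then screened through a
    cascade of false-positive filters: target site duplication (TSD)
    verification in asymmetric flanking windows, position-specific copy-number
    profiles with boundary refinement and truncated/shifted/extended profile
    rejection, ncRNA exclusion, tandem-repeat fraction and terminal inverted
    repeat (MITE) filters. Surviving intact elements are clustered into a
    nonredundant seed library used to annotate the whole genome under a
    divergence cap. Includes base-, element- and seed-level evaluation against
    a reference annotation and a synthetic genome simulator with planted SINEs
    and decoy repeats for desk-scale validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
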