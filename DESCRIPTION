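Package: bescan
Title: Strand-Aware Targetability Prediction for Cytosine Base Editors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts which single-nucleotide variants can be created
    (C-to-T) or corrected (T-to-C) by a configurable panel of CRISPR
    cytosine base editors. Implements strand-aware enumeration of
    protospacer+PAM placements that put the target cytosine inside an
    editor's editing window, bystander and preferential-target
    classification, ClinVar-style pathogenic SNV filtering, gRNA spacer
    design from genomes or free sequence, and amplicon deep-sequencing
    editing-outcome metrics (substitution and indel frequencies, product
    purity, reference-normalised efficiency, one-tailed rank-sum test).
    Ships a synthetic-fixture generator with an independent brute-force
    oracle for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
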