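Package: transclean
Title: Transgene-Free Verification of Genome-Edited Strains from
    Whole-Genome Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Verifies that a genome-edited strain carries no residual
    vector or plasmid DNA by counting, for every position of the vector
    sequence, the whole-genome sequencing reads that share a canonical
    20-mer with that position, and comparing edited-sample counts against
    a wild-type control with a per-position G-test of independence
    (critical value 6.634 at the 1% level). Significant runs of positions
    are called as peaks and classified as foreign-DNA candidates,
    target-mutation signatures at the gRNA spacer, or shared endogenous
    sequence, yielding a foreign-free verdict. Companion tools call
    CRISPR indels at the protospacer/PAM window from amplicon sequences
    via affine-gap global alignment, assign the nucleus of origin of an
    amplicon from catalogued SNVs between parental monokaryons, and
    predict genomic-PCR presence/absence in silico. A paired-end read
    simulator generates complete synthetic experiments (progenitor and
    derived genomes, annotated vector, edits, foreign-fragment
    insertions, reads) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
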