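Package: planartx
Title: Desk-Scale Dual-Platform Transcriptome Discovery with Split-Read
    Rescue on Fragmented Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained re-implementation, at simulation scale, of a
    dual sequencing-platform transcriptome discovery pipeline for organisms
    with highly fragmented, A/T-rich genome assemblies such as the planarian
    Schmidtea mediterranea.  Provides a synthetic-data generator with known
    gene-model and expression truth; a seed-and-extend short-read mapper with
    annotation-guided split reads; a coverage-island transcript assembler;
    iterative "super-gene" split-read rescue for de novo splice-junction
    discovery; a greedy overlap-layout long-read assembler with
    isogroup/isotig reporting, N50 and saturation analytics; rule-based
    merging of long-read and short-read transcript sets with a 95%-identity /
    50-nt homology screen; six-frame longest-ORF classification; and RPKM
    quantification with a Baggerly-style weighted proportion test for an
    irradiated-versus-intact differential expression contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    rtracklayer,
    data.table,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
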