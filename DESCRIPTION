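Package: elemevo
Title: Evolutionary Origination and Maturation Analysis of DNA Regulatory
    Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for decomposing the evolutionary origin of transcriptional
    regulatory elements (silencers and enhancers) that overlap or flank an
    open reading frame.  Provides a codon-constraint overlay that partitions
    element bases into first/second codon positions and wobble positions,
    cross-species invariance profiles and a tripartite base classification,
    nearest-neighbor GC-bias tables around invariant bases, GC/CpG
    composition statistics with a CpG cluster enrichment test, literal and
    bounded-wildcard motif scanning, tandem-repeat detection, affine-gap
    global pairwise alignment with percent identity, identity-based
    origination dating along a dated species ladder, completion-species
    calls, and a forward simulator of ortholog ladders with known
    ground-truth constraint classes and a GC-biased mutation kernel at
    neighbors of frozen positions.  Ships the printed element sequences of
    the human SMIM45 locus as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
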