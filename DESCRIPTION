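Package: skimplast
Title: Plastome Genome Skimming: Reference-Guided Drafts, Assembly QC and
    Alignment-Free Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational core of a herbarium genome-skimming workflow for
    chloroplast (plastid) genomes. Provides reference-guided draft
    construction from contigs (maximal-exact-match anchoring and colinear
    chaining, reference selection, ordering/orienting/joining), assembly
    error scoring and good/poor classification, biological diagnostics
    (GC content, maximal repeats, inverted-repeat detection, non-IR repeat
    content), alignment-free species identification by average common
    substring ranking, simulated-PCR extraction of rbcL/matK barcodes,
    read pre-processing (adapter trimming, k-mer depth normalization,
    pair merging, pseudo-mapping depth), and a synthetic plastome/read
    simulator so the whole pipeline runs end-to-end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
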