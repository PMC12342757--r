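Package: msaRefine
Title: Post-Processing Refinement of Protein Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Refines an existing protein multiple sequence alignment without
    recomputing it from scratch. The alignment is segmented at its first and
    last gap-free columns into head, target and tail regions; the target
    region is recursively re-optimized by vertical iterative realignment
    against a pluggable inner aligner (MUSCLE5, MAFFT FFT-NS-I, or a built-in
    deterministic center-star aligner), with competing sub-alignments
    arbitrated by a sum-of-pairs objective (BLOSUM62/PAM250 plus flat gap
    penalties). Includes Q/TC accuracy scoring against reference alignments
    and a synthetic protein-family simulator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
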