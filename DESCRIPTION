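Package: pirnascape
Title: Simulation and Analysis of Testis Small-RNA (piRNA) Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for profiling PIWI-interacting RNA (piRNA) populations in
    two-condition small-RNA sequencing experiments: candidate piRNA calling by
    the 1U/10A rule, ncRNA class composition and length profiles, positional
    nucleotide-bias and ping-pong (10-nt 5' overlap) signature statistics,
    genomic-origin category assignment (repeat/gene/other), TPM-based
    differential expression with fold-change and p-value thresholds, and
    construction and export of bipartite piRNA-mRNA regulatory networks. A
    fully parameterised synthetic-data generator produces genomes, annotated
    libraries, alignments and count matrices with ground-truth labels for
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
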