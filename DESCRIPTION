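Package: allorep
Title: Alloreactive T-Cell Receptor Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing directly and indirectly alloreactive
    T-cell receptor beta-chain repertoires from bulk TCR-seq clonotype tables.
    Reads MiXCR and AIRR Rearrangement exports, TMM-normalizes clonotype count
    matrices, calls fold-expanded clonotypes with an empirical-Bayes
    negative-binomial two-model posterior, quantifies repertoire overlap with
    the Morisita-Horn index across expansion thresholds, clusters CDR3 amino
    acid sequences by Hamming distance 1, discovers GLIPH2-style specificity
    patterns (local motifs and global templates) with exclusive pattern-set
    algebra, computes repertoire features (V-gene usage, spectratype,
    positional amino acid profiles), annotates CDR3s against VDJdb/McPAS-style
    specificity databases, and simulates multi-sample repertoires with planted
    ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
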