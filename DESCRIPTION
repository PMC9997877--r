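Package: dftree
Title: Alignment-Free Gene Clustering from Fourier Power Spectra of DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clusters DNA sequences without alignment by converting each
    sequence into four binary (Voss) indicator signals, taking their
    discrete Fourier transforms, and summarising the power spectra with
    length-invariant moment descriptors. Sequences of very different
    lengths become comparable fixed-length feature vectors, which are
    clustered under four agglomerative linkages (single, complete, UPGMA
    average, WPGMC median) and fused into a single consensus gene tree by
    evidence accumulation over the co-association matrix. Includes a
    seeded synthetic sequence-family generator, Newick and PHYLIP
    distance-matrix export, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    ape,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
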