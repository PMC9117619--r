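Package: skelmap
Title: Skeleton-Based Mapping of Long Noisy Reads by Anchor
    Neighborhood-Graph Chaining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end mapper for long, error-rich single-molecule
    sequencing reads. Exact k-mer matches (anchors) between a read and a
    hash-indexed reference are chained over a distance-constrained
    neighborhood graph with a constant edge reward, so that anchors
    flanking structural variants or error-dense stretches stay in one
    chain; the chain is refined to the densest window, the gaps between
    consecutive anchors are classified as match, deletion, or insertion
    and filled with global or semi-global dynamic programming, and the
    skeleton boundaries are extended so every mapped read is aligned
    end-to-end with zero clipping. Ships a read simulator with an
    indel-dominated error model and structural-variant injection, plus
    the evaluation metrics (correctly mapped reads and bases, aligned
    coverage, consecutiveness, breakpoint spanning, alignment score)
    used to assess such mappers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
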