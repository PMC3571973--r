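Package: blastr
Title: Parse, Store and Query NCBI BLAST Plain-Text Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lossless parser for multi-query NCBI BLAST plain-text
    ("pairwise") reports from blastp, blastn, blastx and psiblast, up to the
    legacy 2.2.26 layout. Builds a hierarchical result model (query,
    iteration, subject alignment, high-scoring segment pair) that retains
    alignments and verbatim header, summary and footer blocks; persists it
    to a single random-access database file keyed by query id; and exposes
    filter, select, sort and export operations over the stored hits that
    reproduce the classic report-manager table formats. A deterministic
    synthetic-report generator with exact ground truth serves as the test
    corpus and round-trip oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    tibble
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
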