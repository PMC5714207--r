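Package: rrbsdesign
Title: In Silico Design of Customised Reduced Representation Bisulfite
    Sequencing Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs reduced representation bisulfite sequencing (RRBS)
    protocols for arbitrary sets of weighted genomic sites of interest.
    Given a genome, a catalog of restriction enzymes grouped into
    isoschizomer families, and a site annotation, the package performs
    IUPAC-aware in silico digestions for every single enzyme and every
    unordered enzyme pair, grid-searches size-selection windows at the
    resolution of the assumed gel-excision error, and ranks candidate
    protocols by enrichment value. Each reported protocol carries the
    number of selected fragments, the recovered-site score, the fold
    reduction in sequencing cost relative to whole-genome bisulfite
    sequencing, and a robustness value quantifying the sensitivity of
    the enrichment to size-selection error. A validation module compares
    predicted site recovery against experimentally observed coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
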