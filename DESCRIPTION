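Package: rad2b
Title: Multiplexed 2b-RAD Library Design, In-Silico Digestion, Read
    Filtering and F2 Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for reduced-representation genotyping with type IIB
    restriction enzymes (2b-RAD). Provides declarative enzyme models and
    IUPAC motif scanning over genomes, extraction and canonicalization of
    the 33-nt BsaXI tags, fixed-window enzyme-landscape simulations,
    inline-barcode and adapter design with amplicon arithmetic and
    overhang-targeting fractions, a two-step sequence-based read filter
    (barcode assignment with one allowed mismatch, positional
    recognition-site matching), restriction-site coverage and saturation
    accounting, and a simplified reference-anchored F2 aa x bb genotype
    caller with missing-rate and chi-square segregation filters. A
    built-in synthetic-data simulator emulates a diploid F2 design end to
    end and emits machine-readable truth tables, so the whole pipeline is
    testable without external data. All user-facing functions take and
    return tibbles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    S4Vectors,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
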