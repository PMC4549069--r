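Package: mitoduplex
Title: Duplex-Consensus Mutation Calling and Mitochondrial Mutation Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for calling ultra-rare mitochondrial DNA mutations from
    duplex-tagged sequencing reads. Reads sharing a double-stranded molecular
    tag are collapsed into single-strand consensus sequences (SSCS), paired
    into duplex consensus sequences (DCS), and piled up against a circular
    mitochondrial reference to yield clonality-tiered variant calls
    (rare, low-heteroplasmic, high-heteroplasmic, homoplasmic). Downstream
    summaries include 12- and 6-type substitution spectra with strand-bias
    tests, 96-class trinucleotide context spectra, cross-sample common and
    unique variant sets, synonymous/nonsynonymous burden under the vertebrate
    mitochondrial genetic code, and the by-chance nonsynonymous expectation.
    A seeded synthetic duplex-read generator with planted truth makes every
    stage testable at desk scale.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
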