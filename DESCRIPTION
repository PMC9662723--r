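Package: poldiv
Title: Batch Standardization of Political Division Names Against a Gazetteer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves 1-3 level political division combinations (country,
    state/province, county/parish) against a gazetteer reference database,
    returning standardized names, ISO/FIPS/HASC codes, gazetteer and spatial
    object identifiers, per-level match methods and scores, and an overall
    match status. Matching works down the administrative hierarchy using a
    cascade of code lookup, exact standard and alternate name lookup, and
    trigram fuzzy matching (Jaccard similarity over padded 3-grams), with
    special-case handling for territories recorded as states and for member
    countries of multinational unions recorded as countries. Includes a
    deterministic synthetic gazetteer generator for tests and demos, parsers
    and writers for the delimited input/output formats, a JSON request
    interface, and a command line tool for batch processing of species
    occurrence location data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
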