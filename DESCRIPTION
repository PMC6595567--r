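Package: rm5tools
Title: Batch Parsing, Normalisation and Curation of RevMan 5 Review Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for evidence-synthesis informatics over RevMan 5 (.rm5)
    systematic-review XML files. Batch-parses a documented subset of the
    RevMan 5.3 dialect into tidy tables, normalises semi-structured free text
    (blinding, allocation, participant counts) with a user-replaceable YAML
    rule engine, harvests and clusters free-text outcome titles into a
    curatable ontology worksheet, marshals every extracted variable into one
    central queryable XML dataset with CSV/JSON exports and summary queries
    (publication-year histogram, participant totals), and writes curated
    contributed-outcome lists back into source reviews idempotently via
    sentinel-delimited blocks. Includes a seeded generator of synthetic .rm5
    corpora with a ground-truth manifest used as the oracle for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
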