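Package: rflpdiet
Title: Diagnostic PCR-RFLP Assay Design and DNA-Barcoding Diet Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing diagnostic PCR-RFLP assays over
    species-labelled DNA barcode voucher libraries and for quantifying
    piscivore diets from stomach-content and stable-isotope records.
    Includes IUPAC-aware restriction-site scanning and fragment-size
    prediction, degenerate-primer in-silico PCR with primer cocktails,
    a dual-priming-oligonucleotide (DPO) blocking-primer outcome model,
    diagnostic-enzyme and parallel-digest search over cut matrices,
    stomach-content diet metrics (percent occurrence, weight, number,
    index of relative importance, Hill-number diversity profiles),
    trophic position from nitrogen isotope ratios, relative weight and
    Fulton's condition factor, and seed-deterministic synthetic-data
    generators for every stage.
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
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
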