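Package: ribotis
Title: Translation Initiation Site Calling and Antigen ORF Detection from
    Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls translation initiation sites (TISs) from
    harringtonine-arrested ribosome profiling footprints aligned to a
    transcriptome, using metagene P-site offset estimation and a negative
    binomial test against a per-transcript background with transcriptome-wide
    false discovery rate control. Extends significant TISs to open reading
    frames (ORFs), classifies them relative to the annotated coding sequence
    (upstream, internal in/out-of-frame, downstream, lncRNA), matches a
    catalog of T-cell antigen ORFs against per-sample detections, and reports
    class-wise detection sensitivity with expression stratification. Includes
    a synthetic-data generator that plants ORFs of every class with known
    ground truth so each stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
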