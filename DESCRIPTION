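Package: modbindr
Title: Quantifying Transcription-Factor Binding to Modified DNA Baits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A label-free proteomics pipeline for DNA-pulldown experiments in
    which nuclear extracts are incubated with synthetic DNA baits carrying
    cytosine in its unmodified (5C), methylated (5mC), hydroxymethylated
    (5hmC) or formylated (5fC) state.  Peptide-level intensity tables are
    turned into protein-level iBAQ and fraction-of-total (FOT) quantification
    matrices; DNA-modification-restricted binders (dmrTFs) are called with a
    geometric-mean fold-change rule; consensus "readers" are nominated across
    cellular contexts; binding preference is aggregated and tested at the
    TF-family and DNA-binding-domain level; developmental time courses are
    summarized into temporal modules; and bait-specific TF-target-gene
    networks are filtered against methylome, hydroxymethylome and
    transcriptome statistics.  A synthetic-data module generates complete
    study designs with planted readers so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
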