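Package: seedscreen
Title: Design and Analysis of Synthetic-Exon Knock-In Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering synthetic-exon expression-disruptor (SEED)
    knock-in cassettes and for analysing pooled knock-in mutagenesis screens.
    Covers homology-directed repair template assembly with splice-frame
    validation, BLOSUM-guided scanning and saturation mutagenesis library
    design, exact-match amplicon read quantification, sort-seq bin-ratio
    enrichment scoring for antibody epitope mapping, droplet digital PCR
    translocation frequencies, and a synthetic screen generator with recorded
    ground truth so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
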