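Package: splicetide
Title: Transcript-Centric Alternative Splicing Analysis for Long-Read Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates alternative splicing events (alternative promoters,
    alternative 5'/3' splice sites, cassette exons, retained introns and
    alternative transcription end sites) from collapsed long-read transcript
    models, fits a Bayesian beta model for differential isoform usage between
    two conditions within promoter groups, propagates percent-spliced (PS)
    log2 fold-changes from transcripts to the events they embed, classifies
    coding consequences (ORF overlap, stop-codon position, Pfam-domain
    alteration), and provides the contingency statistics layer (exact
    binomial imbalance, Fisher 2x2, chi-square with Yates correction and
    standardized residuals, Bonferroni adjustment) used to summarise such
    analyses. A synthetic-data generator emulates collapsed transcriptome
    GTFs and replicate abundance tables with designed events and usage
    shifts so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
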