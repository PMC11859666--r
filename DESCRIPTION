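Package: pseudom6a
Title: Integrative m6A Profiling and Prioritization of Pseudogene-Derived RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for profiling N6-methyladenosine (m6A)
    modification on pseudogene-derived RNAs and prioritizing candidate
    oncogenic pseudogenes. Provides windowed IP-versus-input peak calling for
    MeRIP-seq style count data, tumour-versus-normal differential methylation,
    HOMER-style region annotation and metagene profiles, discriminative
    ungapped motif discovery against shuffled controls with RRACH matching,
    negative-binomial differential expression, pseudogene-parent (ceRNA)
    correlation analysis stratified by relative m6A level, univariate Cox
    prognostic screening with Kaplan-Meier curves, miRNA seed-site and shared
    sponge detection, ORF finding, and a multi-omics candidate filter cascade.
    A seeded synthetic multi-omics generator reproduces the statistical
    structure every stage assumes, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    survival,
    minpack.lm,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
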