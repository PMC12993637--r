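Package: vertmicro
Title: Mother-Daughter Vaginal Microbiota Similarity and Strain
    Transmission Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify vertical (mother-to-daughter) transmission
    of the vaginal microbiota. Computes Yue-Clayton theta community
    distances from mothur-style shared OTU tables, groups them within
    subject, within mother/daughter pair and between pairs, and tests for
    birth-mode effects with rank-based statistics and principal
    coordinates ordination. Applies a hard-filter and positional-mask
    cascade (quality thresholds, indel proximity, phage/repeat regions,
    core genome, recombinant tracts) to per-isolate variant calls and
    computes recombination-filtered pairwise SNP distances. Estimates in
    vivo bacterial doubling times and per-year mutation accumulation from
    SNP counts under a shared-ancestor molecular clock. Includes
    Dirichlet-multinomial paired-community and clonal genome-divergence
    simulators so the full pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
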