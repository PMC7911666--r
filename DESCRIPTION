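Package: rtswitch
Title: Replication Timing Profiles and Switching-Domain Detection from Repli-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide replication timing (Repli-seq) analysis: per-million
    normalization of early/late S-phase read counts in fixed 5-kb bins,
    log2(early/late) ratio profiles smoothed by fixed-span local regression,
    fixed-position 200-kb segment summaries, replicate-calibrated detection of
    early-to-late and late-to-early switching segments with empirical p-values
    and Storey q-value FDR control, integration of timing changes with ChIP-seq
    enrichment and gene-expression changes, and DNA-combing fiber analysis
    (lambda-DNA stretch calibration, replication fork speed, inter-origin
    distances). Includes a synthetic-data generator with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
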