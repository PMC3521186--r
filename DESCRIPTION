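Package: hapbop
Title: Single-Individual Haplotype Assembly by Balanced Optimal Partition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the two haplotypes of a diploid individual from
    aligned sequencing fragments encoded as an m x n SNP matrix over {0,1,-}.
    Implements the Balanced Optimal Partition (BOP) model, which blends the
    minimum-error-correction (MEC) and maximum-fragments-cut (MFC) objectives
    through a weight factor, and solves it with H-BOP, a beam-bounded
    left-to-right dynamic program over sorted fragments. Also provides exact
    brute-force solvers for small instances, a fragment simulator with
    configurable error and gap rates, connected-component block decomposition,
    fragment-file readers and writers (HapCUT-style and dense dialects), and
    phasing accuracy metrics: per-block switch errors, switch error rate,
    phased haplotype length, and quality-adjusted N50 (QAN50).
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
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
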