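Package: aneuadapt
Title: Quantifying Adaptation to Aneuploidy from Copy-Number, Proteome and
    Growth Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy analysis pipeline for studying how cells adapt to
    chromosome gains. Provides arm-level aneuploidy scoring from segmented
    log2 copy-number ratios (binary segmentation with permutation-based
    change-point acceptance), a total-relative-DNA heuristic, residual
    bootstrap quantification of growth-curve area under the curve,
    moderated differential protein abundance with arm-level dosage
    compensation estimates, per-gene correlation of tumor-minus-normal
    expression changes with tumor aneuploidy scores (AADEPT), rank-based
    annotation enrichment in one or more dimensions, hypergeometric
    overrepresentation with an enrichment strength statistic, and a
    permutation-calibrated protein relevance score for adaptation patterns.
    A synthetic-data generator produces karyotypes, binned copy-number
    profiles, patient cohorts, cell-line proteomes and growth curves with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
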