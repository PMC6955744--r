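Package: aortaDE
Title: Case-vs-Case Transcriptomic Contrast of Abdominal Aortic Aneurysm
    Against Aorto-Iliac Occlusive Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for contrasting bulk expression profiles of
    abdominal aortic aneurysm (AAA) tissue against aorto-iliac occlusive
    disease (AOD) tissue, the best-match control sharing atherosclerotic risk
    factors.  Covers quantile normalization, hybridization-batch centering,
    PCA and hierarchical-clustering sample QC with discordant-sample
    flagging, per-probe two-group testing with signed linear fold changes and
    median probe-to-gene collapse, removal of sex-linked genes derived from
    an external control cohort, upstream-regulator activation inference
    (activation z-score and hypergeometric overlap p-value), gene-set
    overrepresentation, a two-track candidate prioritization workflow
    (expression bins, upregulation filter, annotation marking, fold-change
    and z-score ranking to a combined 60-gene list), and the companion
    clinical-cohort and delta-delta-Ct qPCR statistics.  A synthetic-data
    module generates every input with planted ground truth so the full
    pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
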