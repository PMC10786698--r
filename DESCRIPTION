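Package: scoliquant
Title: Quantitative Analyses for Glycinergic Scoliosis Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable implementation of the quantitative
    procedures used to study glycine-transporter-linked idiopathic
    scoliosis: bilateral spinal calcium-activity quantification
    (dF/F extraction, event detection, left-right alternation index,
    event frequency, total signal), zebrafish body-curvature
    morphometrics (theta angle, >= 10 degree penetrance, dose-response
    and rescue comparisons), surface-EMG preprocessing (band-pass,
    zero mean, reference-guided ECG removal, bending normalization),
    rare-variant cohort allele-frequency association, radioligand
    glycine-uptake normalization, and hypergeometric gene-set
    enrichment. A synthetic-data module generates every input the
    pipeline consumes, with the statistical structure the analyses
    assume, so the whole pipeline is exercisable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    zoo,
    signal,
    pracma,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
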