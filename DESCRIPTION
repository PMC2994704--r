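Package: pfmtransfer
Title: Predicting Quantitative DNA-Binding Specificities of Transcription
    Factors by Similarity-Metric Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts position frequency matrices (PFMs) for transcription
    factors without experimentally characterised binding specificity. A
    per-superclass support vector regression model learns a PFM-similarity
    metric from 30 pairwise sequence-derived features of DNA-binding
    domains; the learned metric is then used to transfer and merge PFMs
    from reference factors to query factors, with nearest-neighbour and
    random baselines, outlier filtering, STAMP-style ungapped motif
    alignment and merging, an exact overlap-probability PFM similarity
    score, and a minimal log-odds promoter scanner with background
    calibrated cutoffs. A seeded synthetic corpus generator produces
    transcription factor families whose domain-sequence divergence is
    statistically coupled to motif divergence, so the whole pipeline can
    be exercised and evaluated without proprietary motif databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
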