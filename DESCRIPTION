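Package: trendmeta
Title: Two-Cohort Transcriptomic Discovery with Ordered-Trend Screening
    and Weighted-Z Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for two-cohort transcriptomic discovery in
    staged disease such as diabetic kidney disease. Screens blood expression
    for genes whose level rises or falls monotonically across ordered
    clinical stages with the Jonckheere-Terpstra trend test; combines
    heterogeneous case/control tissue microarray datasets with one-tailed
    t-derived signed Z-scores, probe-to-gene collapse and the weighted
    Z-method (eGWAS style, |Z| > 5 screening); intersects the two gene sets
    with hypergeometric enrichment and runs over-representation analysis
    against GMT gene-set collections with Benjamini-Hochberg FDR control.
    Includes two-color array normalization (within-array loess,
    between-array intensity quantile), PCA outlier flagging, ANOVA gene
    filtering, and a synthetic-data generator that plants recoverable
    trend, differential-expression and overlap signals for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
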