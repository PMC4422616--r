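Package: fpitools
Title: Fishery Performance Indicators: Schema, Scoring, Aggregation and
    Cross-Fishery Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the Fishery Performance Indicators (FPIs), a
    rapid-assessment instrument for triple-bottom-line evaluation of
    fisheries. Provides a machine-readable schema of the instrument (68
    outcome metrics braided into triple-bottom-line and sector
    partitionings, 54 enabling-factor metrics in 15 dimensions across 5
    components), threshold-based metric scoring, unweighted and
    quality-weighted aggregation to dimension and indicator scores,
    rank-based nonparametric cross-fishery comparison (exact and
    approximate Wilcoxon/Mann-Whitney rank-sum tests, Spearman rank
    correlation, group dimension profiles), delimited-text case-study
    input/output, a latent-threshold synthetic case-study generator for
    testing, and plain-text/HTML report rendering with a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
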