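Package: qgdemar
Title: Quantile-Gaussian Deconvolution for Probe-Level Factorial Microarray Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially expressed microarray probes by fitting a
    Gaussian empirical null to the central quantiles of a discrimination
    variable (probit-plot regression on the inner order statistics) and
    calling per-tail outliers at a target tail-area false discovery rate.
    Builds the discrimination variables of a 2x2 factorial design at probe
    level (log-ratios, super-ratio interaction statistics, condition
    differences, log2 quotients), estimates per-tail FDR with an NDAS (not
    detectable as significant) outcome when no threshold sustains the
    target, applies positional-insertion ("delta-N" control) and operon
    blacklist corrections to detection lists, partitions gene lists into
    Venn components, and simulates spike-in factorial datasets with known
    truth for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
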