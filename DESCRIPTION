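Package: crosstrait
Title: Cross-Trait Genetic Correlation, Mendelian Randomisation and
    Gene-Level Overlap from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for cross-trait analysis of GWAS summary
    statistics: harmonisation and quality control of per-variant summary
    records, global genetic correlation by bivariate LD score regression
    with free intercepts and block-jackknife standard errors, local
    genetic correlation on semi-independent LD blocks with Monte-Carlo
    confidence intervals and a completely-shared criterion, bidirectional
    univariable and multivariable two-sample Mendelian randomisation
    (IVW, MR-Egger, weighted median, Cochran's Q, leave-one-out,
    MR-PRESSO), and gene-level overlap statistics (one-sided exact
    binomial overlap test, Fisher's combined probability classification).
    A synthetic-data module generates every input the pipeline consumes
    -- LD panels, paired summary statistics with known global and local
    genetic covariance, gene-level P tables, and instrument-level MR
    data -- so all stages are testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
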