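Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("mrpipe", "developers", role = c("aut", "cre"),
    email = "mrpipe@example.org")
Description: Complete two-sample Mendelian randomization workflow for GWAS
    summary statistics: instrument selection (genome-wide significance
    filtering, LD clumping, proxy substitution, F statistics), allele
    harmonization with palindromic-SNP frequency inference, five causal
    estimators (inverse-variance weighted, MR-Egger, weighted median,
    maximum likelihood, per-SNP Wald ratios) with Cochran's Q / I-squared
    heterogeneity and Egger-intercept pleiotropy diagnostics, leave-one-out
    analysis, MR-PRESSO global/outlier/distortion tests with outlier-corrected
    re-estimation, multivariable MR with difference-method mediation
    decomposition, analytic power calculation, Bonferroni classification,
    and a synthetic GWAS summary-statistics generator with known causal
    structure for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
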