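Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("mrpipe", "maintainers", email = "mrpipe@example.org",
    role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization workflow built on
    GWAS summary statistics: instrument selection (p-value thresholding,
    greedy LD clumping, confounder screening against a local annotation
    table), instrument-strength metrics (R-squared and F statistics),
    harmonization of effect alleles across studies (strand flips,
    palindromic variants), causal estimation by inverse-variance-weighted
    meta-analysis of Wald ratios, MR-Egger regression and the weighted
    median, and a sensitivity suite (Cochran's Q, Egger intercept,
    MR-PRESSO global/outlier/distortion tests, leave-one-out, forest and
    funnel plot data). Ships a synthetic summary-statistic generator with
    known ground truth so every stage is testable offline, plus a
    config-driven pipeline and command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
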