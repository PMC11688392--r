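Package: metabomr
Title: Two-Sample Mendelian Randomization for Circulating Metabolic Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    panels of circulating metabolic biomarkers against disease outcomes such
    as breast cancer and its estrogen-receptor subtypes. Provides GWAS
    summary-statistics input/output and effect-allele harmonization,
    instrument selection (genome-wide significance filtering, greedy LD
    clumping, F-statistic weak-instrument exclusion), four causal estimators
    (inverse-variance weighted, MR-Egger, weighted median, weighted mode),
    sensitivity diagnostics (Cochran's Q with a fixed/random model rule,
    MR-Egger intercept test, MR-PRESSO outlier resampling, Steiger
    directionality, leave-one-out, funnel-plot data), Benjamini-Hochberg
    false discovery rate control across a biomarker panel, and a synthetic
    GWAS summary-statistics generator with known ground truth for end-to-end
    validation.
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
    withr
Config/testthat/edition: 3
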