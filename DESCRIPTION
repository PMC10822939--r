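Package: triomr
Title: Three-Leg Two-Sample Mendelian Randomization with Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization on GWAS summary
    statistics, organised around the three-leg design used to probe whether
    the gut microbiota mediates the effect of inflammatory bowel disease on
    its extraintestinal manifestations. Implements instrument selection
    (p-value threshold, greedy LD clumping, F-statistic and minor-allele
    frequency filters, palindromic-variant removal), effect-allele
    harmonization, inverse-variance-weighted estimation with Cochran's Q
    model selection, MR-Egger regression, the bootstrap weighted median,
    MR-PRESSO global/outlier/distortion tests, leave-one-out domination
    screening, the Steiger directionality test, product-of-coefficients
    mediation, and a rank-wise Bonferroni study pipeline. A summary-level
    GWAS simulator with known causal truth supports calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
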