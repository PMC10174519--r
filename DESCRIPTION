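Package: gxladjust
Title: Genotype-by-Lab Adjusted Inference for Single-Lab Phenotyping Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing and improving the replicability of
    single-laboratory rodent phenotyping results under the Random Lab
    Model. Estimates within-group, between-lab and genotype-by-lab
    (GxL) interaction variance components from multi-lab data by REML,
    derives the dimensionless GxL factor, applies the GxL-adjusted
    t-test with Satterthwaite degrees of freedom to single-lab genotype
    comparisons (and its treatment-contrast extension), classifies
    comparisons into six replicability categories with exact binomial
    summaries of type-I replicability error and power, computes
    GxL-aware power and sample sizes, and simulates multi-lab
    phenotyping datasets for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
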