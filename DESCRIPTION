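Package: triogrs
Title: Maternal Genetic Risk Score Contrasts in Case-Parent Trios
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing maternal genetic effects on congenital heart
    defects with case-parent trios. Computes weighted genetic risk scores
    (GRS) for hypertension, type 2 diabetes and obesity in the parents of
    affected children, contrasts mothers (as cases) against fathers (as
    controls) by mean comparison and by paternal-percentile dichotomization
    with Fisher's exact odds ratios, screens single-SNP association p-values
    against per-condition Bonferroni thresholds, produces cohort descriptive
    tables, and simulates trio cohorts with known maternal-GRS effects and
    affected-child ascertainment so that the design's type-I error and power
    can be measured.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
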