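Package: optrend
Title: Optimal Trend Tests for Case-Control Genetic Association Under
    Heterogeneous Genetic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generalized Cochran-Armitage trend tests for 2x3 case-control
    genotype tables with a model-derived optimal heterozygote coefficient.
    Implements a five-parameter genetic effect model (allele frequency,
    Hardy-Weinberg disequilibrium, mean allele relative risk, its coefficient
    of variation, and a genetic-model parameter) that yields expected case and
    control genotype frequencies under person-to-person heterogeneity of the
    relative risk; the trend coefficient maximizing the expected chi-square
    statistic; a weighted multi-coefficient summary test with a
    mixture-of-chi-squares null distribution (Imhof-type quadrature with a
    Satterthwaite fallback); and Monte-Carlo machinery for sample-size
    calculation, type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
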