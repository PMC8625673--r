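Package: aldaphen
Title: Lithium Response Phenotyping from the Alda Scale with CHAID Trees
    and Candidate-Gene Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for operationalizing lithium-response phenotypes from the
    retrospective Alda scale and comparing their association signals with
    candidate circadian-gene polymorphisms. Implements the five established
    phenotyping strategies (Total Score, dichotomous good/non-responder
    categories, the A-score restricted to low-B-score cases, and a
    tree-derived best-estimate category with its good-response probability),
    a from-scratch CHAID classification-tree builder with Bonferroni-adjusted
    chi-square split selection and cross-validation, genotype quality control
    (minor allele frequency, call rates, heterozygosity outliers,
    Hardy-Weinberg equilibrium, LD-pruned best-SNP selection), non-parametric
    single-SNP association scans under dominant and codominant codings,
    diagnostic concordance metrics, a noncentral-t two-sample power
    calculator, and a synthetic cohort generator with plantable
    genotype-to-response effects.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
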