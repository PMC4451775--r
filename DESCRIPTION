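Package: snpmeta
Title: Genetic-Model Meta-Analysis of Case-Control SNP Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of case-control single nucleotide
    polymorphism (SNP) association studies from per-study genotype counts.
    Builds 2x2 exposure tables under the standard genetic models (allele,
    dominant, recessive, homozygous, heterozygous), estimates per-study odds
    ratios with Haldane-Anscombe zero-cell correction, pools them with
    inverse-variance fixed-effect and DerSimonian-Laird random-effects models,
    and quantifies heterogeneity with Cochran's Q and I-squared. Includes
    subgroup analysis, leave-one-out sensitivity analysis, weighted
    meta-regression with permutation p-values, Egger's regression, Rosenthal's
    classic fail-safe N, funnel-plot exports, Hardy-Weinberg quality control,
    and a Hardy-Weinberg genotype-count simulator for calibration studies.
    Ships the cohort table of a published meta-analysis of TLR4 rs4986790A>G
    and rs4986791C>T polymorphisms and inflammatory bowel disease as a worked
    fixture.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
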