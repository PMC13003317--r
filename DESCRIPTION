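Package: cnfgwas
Title: Combined-Phenotype Association Search for Genetic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Finds, for a given binary genetic variant, the logical
    combination of binary phenotypes (a conjunctive normal form with K
    clauses of up to L phenotypes each) that maximises a monotone
    association statistic such as the one-sided Fisher exact test.  The
    search is exact: candidate combinations are explored through a mixed
    integer linear programme whose significance-threshold constraint is
    encoded as a simplified piecewise-linear lower boundary on the
    co-occurrence count.  Includes a lossless subject-collapse
    preprocessor, a triage/optimisation pipeline over many variants with
    discovery/validation splitting, a single-phenotype GWAS baseline, a
    Cochran-Mantel-Haenszel check against single-phenotype confounding,
    and a simulation module generating noisy planted-CNF pseudo-SNPs
    among frequency-matched decoys for power evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    reticulate,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    withr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
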