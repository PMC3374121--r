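Package: yhapassoc
Title: Y Chromosome Haplogroup Case-Control Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control association analysis of Y chromosome haplogroups.
    Models the Y haplogroup phylogeny with its defining biallelic markers,
    assigns men to haplogroup branches from hemizygous marker calls with
    quality control tailored to the Y chromosome, imputes untyped branches
    from ancestor and sibling nodes, tests each branch bipartition with a
    covariate-adjusted 1-df score test (Fisher exact fallback for sparse
    tables), pools study-level odds ratios by inverse-variance fixed-effect
    meta-analysis, and computes power for haploid allelic tests. A synthetic
    cohort generator with per-study haplogroup frequency profiles, a logistic
    disease model, population-substructure clusters and genotyping error
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
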