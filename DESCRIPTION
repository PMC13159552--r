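Package: glyrep
Title: Cross-Platform Replication of Plasma N-Glycome QTLs
Version: 0.1.0
Authors@R:
    person("glyrep", "developers", email = "glyrep@example.org", role = c("aut", "cre"))
Description: Tools for replicating glycosylation quantitative trait loci
    (glyQTLs) across heterogeneous glycomics platforms. Implements per-trait
    linear association on rank-transformed phenotypes, fixed-effects
    inverse-variance-weighted meta-analysis, a multivariate omnibus test from
    single-trait summary statistics, weighted Cauchy (ACAT) aggregation of
    p-values across glycan-trait panels, Fisher product combination across
    measurement platforms with a Bonferroni replication decision, glycan
    composition parsing and derived-trait algebra, glycan-aware locus
    annotation and gene prioritization, and a synthetic-data generator
    emulating multi-cohort, multi-platform glycomics GWAS inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
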