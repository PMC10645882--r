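Package: hemonet
Title: Comparative Gene Co-Expression Network Analysis of Hematopoietic Cancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares gene co-expression networks (GCNs) from
    RNA-Seq count cohorts of hematopoietic cancers and normal bone marrow.
    Provides count filtering and normalization (TMM, GC/length and
    between-lane full-quantile), co-expression inference by discretized
    mutual information and Spearman correlation with permutation p-values,
    network topology statistics (intra-chromosomal "cis" edge fractions
    across cutoffs with Kolmogorov-Smirnov comparison, biotype interaction
    fractions, component spectra, k-way network intersection), persistent
    community detection over a Louvain resolution sweep, a simplified
    negative-binomial Wald differential-expression stage, hypergeometric
    gene-set over-representation, and a community-level differential
    expression trend statistic. Includes a synthetic-cohort generator with
    planted co-expression modules and known fold changes so the full
    pipeline can be exercised against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    igraph,
    edgeR,
    limma,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
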