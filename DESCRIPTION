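Package: polyTE
Title: Translatome Analysis of Polysome-Profiling RNA-Seq Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired polysomal (P) and total (T) RNA-seq count
    matrices from polysome-profiling experiments. Implements trimmed mean of
    M-values (TMM) scaling factors, negative-binomial exact-style two-group
    differential expression with method-of-moments dispersion estimation and
    Benjamini-Hochberg adjustment, a per-gene translational-efficiency (Te)
    statistic with z-score classification of translationally activated and
    inactivated genes, a four-way transcriptional/translational gene
    classification, set intersections across cell lines, hypergeometric
    over-representation analysis against GMT gene-set collections, and PCA
    sample diagnostics. A synthetic polysome-profiling count generator with
    planted transcriptional, translational, buffered and null regulation
    classes makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
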