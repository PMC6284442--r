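Package: shapesym
Title: Statistical Shape Modelling and Bilateral Asymmetry Analysis of
    Paired 3D Point Sets
Version: 0.1.0
Authors@R:
    person("shapesym", "developers", email = "shapesym@example.org",
           role = c("aut", "cre"))
Description: Tools for studying bilateral shape (a)symmetry of paired
    left/right anatomical structures represented as corresponded 3D point
    sets. Provides mirroring and iterative groupwise similarity alignment,
    principal component shape models with parallel-analysis component
    retention, distance-based permutation tests of group location,
    variance-covariance scale and variance-covariance orientation
    (principal angles / Grassmann projection metric), side-pooled analyses
    (Kolmogorov-Smirnov normality screening, age-adjusted ANCOVA with
    Bonferroni correction, two-way random-effects single-measurement
    absolute-agreement intraclass correlation), a synthetic paired-shape
    generator with recorded ground truth, readers and writers for ASCII
    PLY/OFF/STL meshes and CSV landmark tables, and a config-driven
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
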