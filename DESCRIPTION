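Package: generank
Title: Ranking and Prioritising Genes with Desirability Functions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-criteria ranking of features from -omics experiments
    using desirability functions. Per-gene statistics (p-values, fold
    changes, expression levels, annotations) are mapped onto a continuous
    0-1 desirability scale with piecewise-linear or categorical mapping
    functions, combined into an overall desirability with a weighted
    geometric mean, and used to rank, select, and prioritise genes.
    Includes hierarchical fusion of rankings across experiments,
    sensitivity analysis of rank stability under perturbation of cut
    points and weights, a declarative YAML criteria configuration with a
    command-line interface, and a synthetic differential-expression data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
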