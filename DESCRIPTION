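Package: cytovar
Title: Longitudinal Murine Immunophenotyping from Low-Volume Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated analysis of longitudinal peripheral-blood
    immunophenotyping in mice from low-volume flow cytometry panels.
    Ships declarative panel and gating-hierarchy definitions for three
    14-marker panels (myeloid, lymphoid, intracellular), an automated
    hierarchical gating engine with data-driven threshold placement,
    absolute cell-count normalization to cells per microliter of whole
    blood, repeated-measures variance decomposition into intra- and
    inter-individual eta-squared components with minimum-detectable-change
    and sample-size computation, group-comparison statistics for
    challenge studies (paired percent change, pooled t tests, randomized
    block ANOVA, variance-ratio tests, clinical endpoint scoring), and an
    event-level synthetic cytometry generator with known ground truth for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mclust,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
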