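Package: redoxbudget
Title: Electron-Equivalent Budgets and Community Statistics for Anaerobic
    Soil Incubations
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts endpoint chemistry from anaerobic soil incubation
    experiments (HCl-extractable Fe(II), sulfate, headspace methane,
    chlorophenol dechlorination products) into per-bottle electron-equivalent
    budgets over the competing terminal-electron-accepting processes, with
    abiotic-baseline correction, one-way ANOVA group summaries and compact
    letter displays. Also provides the accompanying microbial community
    statistics implemented from first principles: alpha-diversity estimators
    (ACE, Chao1, Simpson, Shannon), generalized UniFrac distances with
    moderation parameter alpha, non-metric multidimensional scaling by
    Kruskal stress-1 minimisation, PERMANOVA, taxon aggregation with
    dominance thresholds, and Benjamini-Hochberg-adjusted Spearman
    taxa-environment associations. A synthetic-data generator emulates the
    three-group by three-amendment incubation design and
    Dirichlet-multinomial OTU tables so the full pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
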