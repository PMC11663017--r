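Package: psyvis
Title: Quantifying Visual Subjective Effects of Psychoactive Substances from
    Narrative Experience Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of visual subjective effects of
    psychoactive substances from narrative self-report text. Reports are
    segmented into sentences, mapped to fixed-dimension embedding vectors
    through a pluggable backend, screened for visual-effect content with a
    ridge-penalised logistic classifier, and scored against a catalogue of
    seed sentences by embedding distance. Inter-substance variation in
    visual-effect profiles is tested with a mean-absolute-pairwise-difference
    dispersion statistic and a label-shuffling permutation null, alongside
    chi-square association tests with Cramer's V effect sizes. A synthetic
    corpus generator with known ground truth supports end-to-end validation
    without access to restricted report archives or commercial embedding
    services.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    xml2,
    jsonlite,
    yaml,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'embedding.R'
    'synthetic.R'
    'classifier.R'
    'categorization.R'
    'corpus.R'
    'methods-accessors.R'
    'stats.R'
    'pipeline.R'
    'psyvis-package.R'
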