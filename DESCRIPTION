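Package: omipair
Title: Differential Gene-Metabolite Association Screening for Two-Group
    Multi-Omics Studies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Integrates paired transcriptome and metabolite-abundance
    profiles from a two-group (case versus case) study design. Provides
    two-group differential expression with an empirical-Bayes moderated-t
    option, expression-matrix preprocessing (quantile normalization, probe
    collapse, low-abundance and missingness filtering, principal component
    analysis), per-pair phenotype-interaction linear models fitted over
    every gene-metabolite pair, signed differential-correlation screening,
    and hypergeometric pathway over-representation for metabolite sets. A
    synthetic-data generator with planted differential genes and planted
    gene-metabolite interactions supports end-to-end validation and power
    analysis without access to the original assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    SummarizedExperiment,
    S4Vectors,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'sampledesign.R'
    'omicsmatrix.R'
    'diffexpr.R'
    'enrichment.R'
    'integration.R'
    'omipair-package.R'
    'preprocess.R'
    'synthdata.R'
    'pipeline.R'
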