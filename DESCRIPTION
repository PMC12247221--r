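Package: SpecSimBench
Title: Benchmarking Infrastructure for MS/MS Spectral Similarity Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to build and audit machine-learning benchmarks for tandem
    mass spectrometry (MS/MS) spectral similarity prediction. Provides
    spectral-library cleaning and metadata harmonization (MGF/CSV/JSON),
    2-D structure standardization with path-based fingerprints and Tanimoto
    similarity, structure-aware train/validation/test splitting that enforces
    coverage of low train-test similarity with a coverage-grid audit,
    All-Pairs and criteria-filtered spectrum-pair dataset construction,
    biased training-pair sampling, retrieval and ranking metrics
    (binned RMSE, Top Candidate Similarity, Top-Rank), a modified cosine
    baseline scorer, and a synthetic-fixture generator so the whole pipeline
    is testable without downloading public libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    arrow,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: MassSpectrometry, Metabolomics, Cheminformatics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'chemstruct.R'
    'cli.R'
    'eval-metrics.R'
    'fingerprints.R'
    'methods.R'
    'modified-cosine.R'
    'pair-builder.R'
    'quality-filters.R'
    'spectra-io.R'
    'split-sampler.R'
    'synthetic-fixtures.R'
    'utils.R'
    'zzz.R'
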