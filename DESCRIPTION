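Package: tetranet
Title: Tetrad-Matched Cross-Disorder Transcriptomics with Consensus
    Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for tetrad-matched, multi-region postmortem
    brain expression studies comparing several psychiatric diagnoses against
    matched controls. Provides per-gene mixed-model ANCOVA with a tetrad
    random intercept and disease-versus-control least-squares-mean contrasts
    (Tukey-Kramer and Benjamini-Hochberg adjustment), directional Fisher's
    exact gene-set enrichment with net enrichment scores, cross-disorder
    enriched-pathway overlap tests, a signed consensus weighted co-expression
    network (topological overlap, quantile-scaled minimum consensus, dynamic
    hybrid tree cut, eigengene-based module refinement and merging,
    module-trait statistics), qPCR reference-gene stability selection with
    geometric-mean normalization, and a synthetic-data generator that
    emulates the matched study design with planted effects for recovery
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    lme4,
    mclust,
    jsonlite,
    knitr
Config/testthat/edition: 3
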