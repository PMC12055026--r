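Package: msngrad
Title: Morphometric Similarity Network Gradients and Their Group,
    Cognitive and Transcriptomic Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds individual-level morphometric similarity networks (MSNs)
    from multi-feature cortical morphometry, decomposes them into diffusion-map
    gradients aligned to a cohort template by Procrustes rotation, and carries
    the aligned gradients through a full case-control analysis: ComBat site
    harmonization, covariate-adjusted general linear model contrasts with
    Benjamini-Hochberg FDR control, Kolmogorov-Smirnov distribution tests,
    weighted graph topology (clustering coefficient, characteristic path
    length), partial correlation and nested cross-validated support vector
    regression against cognitive scores, and a PLS1 transcription-neuroimaging
    association with permutation and bootstrap inference. A synthetic-data
    module generates cohorts, atlas labelings, cognition scores, and gene
    expression matrices with the statistical structure the analysis assumes,
    so the whole pipeline runs and is testable without restricted-access
    imaging or transcriptomic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    igraph,
    yaml,
    sva
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
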