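Package: semdiv
Title: Semantic Diversity of Words from Latent Semantic Analysis Context Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes the semantic diversity (SemD) of words from any
    plain-text corpus by the classic latent-semantic-analysis pipeline:
    fixed-length context chunking, token cleaning and frequency-threshold
    vocabulary construction, log-entropy weighting of the context-by-word
    count matrix, truncated singular value decomposition, and the negative
    log of the mean pairwise cosine similarity among a word's context
    vectors. Includes cluster-separability diagnostics (Calinski-Harabasz
    scores of labelled context vectors against Monte-Carlo random-label
    baselines, exact t-SNE embedding for visualisation) and a synthetic
    topic-corpus generator with planted diverse, narrow and ambiguous words
    so that every stage is testable without licensed corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
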