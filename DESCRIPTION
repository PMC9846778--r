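Package: sigarchetypes
Title: Stability of Mutational Signature Extraction and Archetypal
    Compression of Signature Catalogues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify instability in single-base-substitution (SBS-96)
    mutational-signature analysis. Reads and validates COSMIC-dialect signature
    tables and mutational catalogues; scores pairwise cosine similarity and
    profile flatness and builds average-linkage cluster maps; simulates
    mutational catalogues from known signatures with uniform random exposures
    and multinomial mutation sampling; performs de novo signature extraction by
    repeated Kullback-Leibler non-negative matrix factorisation with
    Hungarian-matching consensus partitioning and silhouette stability scoring;
    evaluates extraction by success frequency, reconstruction error and
    non-negative least-squares refitting; and compresses a signature catalogue
    by archetypal analysis (principal convex hull) with explained-variance
    model selection and archetype-coefficient grouping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    ape,
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
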