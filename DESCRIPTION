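Package: dpucr
Title: Context-Aware Protein Domain Prediction from Profile-HMM Hits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processes candidate protein domain hits (HMMER-style
    per-domain tables) using pairwise domain co-occurrence "context"
    scores. Builds log-odds context networks from domain-architecture
    corpora, selects the score-maximal legal subset of candidate domains
    per protein by exact combinatorial optimization, and ships the
    classical threshold/E-value baselines, CODD-style context filters,
    a shuffled-sequence false-discovery-rate benchmark, an ortholog
    coherence benchmark, and a synthetic fixture generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    stats,
    utils,
    generics,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
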