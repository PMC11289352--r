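Package: lexposure
Title: Lexical Frequency Norms, Diversity Statistics and Vocabulary
    Exposure Simulation for Child-Directed Text Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds wordform and bigram lexicons from directories of
    plain-text transcripts, with frequency per million, Zipf values,
    dispersion (coefficient of variation and deviation of proportions),
    contextual diversity, transitional probabilities and surprisal.
    Computes per-document diversity statistics (STTR, MATTR, words per
    minute) and a sparse document-term matrix with Matrix Market export.
    Includes a seeded Monte-Carlo simulator of cumulative vocabulary-type
    exposure under daily child-directed-speech plus picture-book reading
    scenarios, and a Zipfian synthetic-corpus generator so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tibble,
    readr,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
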