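#' Zipf-scale frequency value
#'
#' The Zipf scale norms word frequency as `log10(frequency per million
#' tokens) + 3`, giving roughly a 1-7 scale on large corpora (small corpora
#' legitimately exceed 7). With `laplace = TRUE` every word is inflated by
#' one occurrence per million before the log, so unattested forms would
#' receive a finite hypothetical value; the default is off, so only attested
#' frequencies are normed.
#'
#' @param fpm Frequency per million tokens. May be omitted if `raw_freq`
#'   and `total_tokens` are given.
#' @param laplace Add one per million before taking the log?
#' @param raw_freq,total_tokens Alternative parameterisation; `fpm` is
#'   computed as `raw_freq / total_tokens * 1e6`.
#' @return Zipf value(s); vectorised over `fpm`.
#' @examples
#' zipf_value(1)     # 3
#' zipf_value(1000)  # 6
#' zipf_value(raw_freq = 50, total_tokens = 5e5)  # 5
#' @export
zipf_value <- function(fpm = NULL, laplace = FALSE, raw_freq = NULL,
                       total_tokens = NULL) {
  if (is.null(fpm)) {
    stopifnot(!is.null(raw_freq), !is.null(total_tokens), total_tokens > 0)
    fpm <- raw_freq / total_tokens * 1e6
  }
  if (laplace) return(log10(fpm + 1) + 3)
  if (any(fpm <= 0)) {
    stop("zipf_value(): fpm must be > 0 unless laplace = TRUE",
         call. = FALSE)
  }
  log10(fpm) + 3
}

#' Coefficient of variation of per-document counts
#'
#' Dispersion as SD/mean of a word's token frequency across corpus texts.
#' The standard deviation is the population SD (divide by n): under that
#' convention a word confined to a single one of n documents attains the
#' scale's exact maximum, sqrt(n - 1).
#'
#' @param per_doc_counts Numeric vector of counts, one per corpus document
#'   (zeros included for documents where the word is absent).
#' @return CoV in `[0, sqrt(n - 1)]`.
#' @examples
#' coefficient_of_variation(c(2, 4))        # 1/3
#' coefficient_of_variation(c(1, 0, 0, 0, 0))  # 2 = sqrt(5 - 1)
#' @export
coefficient_of_variation <- function(per_doc_counts) {
  stopifnot(is.numeric(per_doc_counts), length(per_doc_counts) >= 1L)
  m <- mean(per_doc_counts)
  if (m == 0) {
    stop("coefficient_of_variation(): all-zero count vector", call. = FALSE)
  }
  sqrt(mean((per_doc_counts - m)^2)) / m
}

#' Deviation of proportions (DP)
#'
#' Gries-style dispersion: observed proportions are each document's share of
#' the word's tokens, expected proportions each document's share of the
#' corpus tokens, and `DP = sum(|O - E|) / 2`. 0 means the word is spread
#' exactly in proportion to document sizes; values near 1 mean it is
#' concentrated in a vanishing share of the corpus.
#'
#' @param per_doc_counts Word counts per document.
#' @param doc_sizes Token counts per document (same length).
#' @return DP in `[0, 1]`.
#' @examples
#' deviation_of_proportions(c(4, 0), c(100, 100))   # 0.5
#' deviation_of_proportions(c(3, 1), c(150, 50))    # 0
#' @export
deviation_of_proportions <- function(per_doc_counts, doc_sizes) {
  if (length(per_doc_counts) != length(doc_sizes)) {
    stop("deviation_of_proportions(): length mismatch", call. = FALSE)
  }
  stopifnot(sum(per_doc_counts) >= 1, sum(doc_sizes) >= 1)
  o <- per_doc_counts / sum(per_doc_counts)
  e <- doc_sizes / sum(doc_sizes)
  sum(abs(o - e)) / 2
}

# type-by-document sparse count matrix, rows alphabetical; the shared
# backbone for build_lexicon() and build_dtm()
type_doc_matrix <- function(corp) {
  toks <- doc_tokens(corp)
  all_tokens <- unlist(toks, use.names = FALSE)
  types <- sort(unique(all_tokens), method = "radix")
  i <- match(all_tokens, types)
  j <- rep.int(seq_along(toks), lengths(toks))
  Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(types), length(toks)),
    dimnames = list(types, names(corp$documents))
  )
}

# lexicon order: descending raw frequency, alphabetical among ties
rank_order <- function(freqs, names_) {
  order(-freqs, names_, method = "radix")
}

#' Build the ranked wordform lexicon
#'
#' One entry per distinct wordform with raw frequency, contextual diversity
#' (number of texts containing the word), frequency per million, Zipf value,
#' coefficient of variation and deviation of proportions, ranked by
#' descending raw frequency with alphabetical tie-break. Dispersion is
#' computed over all corpus documents, counting zeros for documents where
#' the word is absent.
#'
#' @param corp A `lex_corpus`.
#' @param laplace Passed to [zipf_value()].
#' @return A `lexicon`: a tibble with columns `rank`, `wordform`,
#'   `raw_freq`, `n_texts`, `fpm`, `zipf`, `cov`, `dp`, and attributes
#'   `total_tokens`, `n_docs`.
#' @export
build_lexicon <- function(corp, laplace = FALSE) {
  stopifnot(inherits(corp, "lex_corpus"))
  X <- type_doc_matrix(corp)
  n <- ncol(X)
  sizes <- doc_lengths(corp)
  total <- corp$total_tokens

  raw <- Matrix::rowSums(X)
  n_texts <- Matrix::rowSums(X > 0)
  fpm <- raw / total * 1e6
  zipf <- zipf_value(fpm, laplace = laplace)

  m <- raw / n
  ex2 <- Matrix::rowSums(X^2) / n
  cov <- sqrt(pmax(ex2 - m^2, 0)) / m

  # DP via the nonzero triplets: sum over docs of |O - E| splits into the
  # nonzero cells (|x/raw - E_j| - E_j each) plus sum of all E_j, which is 1
  e <- sizes / total
  tr <- Matrix::summary(X)
  contrib <- abs(tr$x / raw[tr$i] - e[tr$j]) - e[tr$j]
  dp <- (rowsum_by_index(contrib, tr$i, nrow(X)) + 1) / 2
  dp <- pmin(pmax(dp, 0), 1)

  ord <- rank_order(raw, rownames(X))
  lex <- tibble::tibble(
    rank = seq_along(ord),
    wordform = rownames(X)[ord],
    raw_freq = unname(as.integer(raw[ord])),
    n_texts = unname(as.integer(n_texts[ord])),
    fpm = unname(fpm[ord]),
    zipf = unname(zipf[ord]),
    cov = unname(cov[ord]),
    dp = unname(dp[ord])
  )
  attr(lex, "total_tokens") <- total
  attr(lex, "n_docs") <- n
  class(lex) <- c("lexicon", class(lex))
  lex
}

rowsum_by_index <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Deterministic stub tagger
#'
#' The lemmatiser/POS-tagger is a pluggable interface: any function mapping
#' a token vector to equal-length `lemma` and `pos` vectors. This stub uses
#' a lookup table and falls back to identity lemma plus a default tag, so
#' tagged lexicons are testable without an external model.
#'
#' @param lookup Optional data frame with columns `wordform`, `lemma`,
#'   `pos`.
#' @param default_pos Tag assigned to words not in the lookup.
#' @return A tagger function `function(tokens) list(lemma =, pos =)`.
#' @export
stub_tagger <- function(lookup = NULL, default_pos = "X") {
  if (!is.null(lookup)) {
    lookup <- as.data.frame(lookup)
    stopifnot(all(c("wordform", "lemma", "pos") %in% names(lookup)))
  }
  function(tokens) {
    lemma <- tokens
    pos <- rep(default_pos, length(tokens))
    if (!is.null(lookup) && length(tokens) > 0L) {
      idx <- match(tokens, lookup$wordform)
      hit <- !is.na(idx)
      lemma[hit] <- lookup$lemma[idx[hit]]
      pos[hit] <- lookup$pos[idx[hit]]
    }
    list(lemma = lemma, pos = pos)
  }
}

#' Build a POS-tagged lexicon
#'
#' Runs the tagger over every document and aggregates frequencies by
#' (wordform, lemma, pos). The per-wordform sums over tags equal the
#' untagged raw frequencies. The `word_pos` column (`wordform_TAG`) sorts
#' related words and their readings together.
#'
#' @param corp A `lex_corpus`.
#' @param tagger A function `tokens -> list(lemma, pos)` with equal-length
#'   outputs; see [stub_tagger()].
#' @return Tibble `word_pos`, `wordform`, `lemma`, `pos`, `raw_freq`,
#'   sorted by descending frequency then `word_pos`.
#' @export
build_tagged_lexicon <- function(corp, tagger = stub_tagger()) {
  stopifnot(inherits(corp, "lex_corpus"), is.function(tagger))
  pieces <- lapply(corp$documents, function(d) {
    tg <- tagger(d$tokens)
    if (length(tg$lemma) != length(d$tokens) ||
        length(tg$pos) != length(d$tokens)) {
      stop("build_tagged_lexicon(): tagger returned wrong-length output ",
           "for document '", d$doc_id, "'", call. = FALSE)
    }
    tibble::tibble(wordform = d$tokens, lemma = tg$lemma, pos = tg$pos)
  })
  dplyr::bind_rows(pieces) |>
    dplyr::count(wordform, lemma, pos, name = "raw_freq") |>
    dplyr::mutate(word_pos = paste0(wordform, "_", pos)) |>
    dplyr::arrange(dplyr::desc(raw_freq), word_pos) |>
    dplyr::select(word_pos, wordform, lemma, pos, raw_freq)
}

#' Extract a high-frequency wordlist
#'
#' The first `n` wordforms by frequency rank. With a `pos_filter`, ranking
#' is over the tagged lexicon restricted to entries whose tag is in the
#' filter (e.g. `c("NN", "NNS", "NNP")` for a noun list), aggregating a
#' wordform's frequency over the admitted tags.
#'
#' @param lexicon A lexicon from [build_lexicon()].
#' @param n Number of words requested.
#' @param pos_filter Optional character vector of admissible POS tags.
#' @param tagged Tagged lexicon from [build_tagged_lexicon()]; required
#'   when `pos_filter` is given.
#' @return Character vector of wordforms in rank order.
#' @export
top_n_wordlist <- function(lexicon, n, pos_filter = NULL, tagged = NULL) {
  stopifnot(n >= 1)
  if (is.null(pos_filter)) {
    pool <- lexicon$wordform
  } else {
    if (is.null(tagged)) {
      stop("top_n_wordlist(): pos_filter needs a tagged lexicon",
           call. = FALSE)
    }
    pool <- tagged |>
      dplyr::filter(pos %in% pos_filter) |>
      dplyr::count(wordform, wt = raw_freq, name = "raw_freq") |>
      dplyr::arrange(dplyr::desc(raw_freq), wordform) |>
      dplyr::pull(wordform)
  }
  if (n > length(pool)) {
    warning("top_n_wordlist(): n = ", n, " exceeds available ",
            length(pool), " entries; returning all", call. = FALSE)
    n <- length(pool)
  }
  pool[seq_len(n)]
}

#' Compare two rank-ordered wordlists
#'
#' Set comparison between two high-frequency lists (e.g. a corpus-derived
#' top-100 against a classroom sight-word list): shared membership, the
#' items of each list absent from the other, and aligned ranks for shared
#' items.
#'
#' @param list_a,list_b Character vectors of unique words, rank-ordered.
#' @return List with `n_shared`, `absent_from_a` (items of `list_b` missing
#'   from `list_a`), `absent_from_b` (items of `list_a` missing from
#'   `list_b`), and `shared`, a tibble of `word`, `rank_a`, `rank_b`.
#' @export
wordlist_overlap <- function(list_a, list_b) {
  if (anyDuplicated(list_a) || anyDuplicated(list_b)) {
    stop("wordlist_overlap(): lists must not contain duplicates",
         call. = FALSE)
  }
  shared_words <- intersect(list_a, list_b)
  shared <- tibble::tibble(
    word = shared_words,
    rank_a = match(shared_words, list_a),
    rank_b = match(shared_words, list_b)
  ) |> dplyr::arrange(rank_a)
  list(
    n_shared = length(shared_words),
    absent_from_a = setdiff(list_b, list_a),
    absent_from_b = setdiff(list_a, list_b),
    shared = shared
  )
}

#' Write a lexicon to TSV
#'
#' Columns `rank wordform raw_freq n_texts fpm zipf cov dp`, UTF-8 with a
#' header row.
#'
#' @param lexicon A lexicon tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon_tsv <- function(lexicon, path) {
  readr::write_tsv(
    lexicon[c("rank", "wordform", "raw_freq", "n_texts",
              "fpm", "zipf", "cov", "dp")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Write a tagged lexicon to TSV
#'
#' Columns `word_pos lemma pos raw_freq`.
#'
#' @param tagged Tagged lexicon tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tagged_lexicon_tsv <- function(tagged, path) {
  readr::write_tsv(tagged[c("word_pos", "lemma", "pos", "raw_freq")],
                   path, progress = FALSE)
  invisible(path)
}
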