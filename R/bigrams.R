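#' Adjacent word pairs of a document
#'
#' All ordered pairs of adjacent tokens within a document: a document of L
#' tokens yields L - 1 pairs, and no pair ever spans a document boundary.
#' No sentence segmentation is applied — caption-style transcripts carry
#' unreliable punctuation — so adjacency is within-document only.
#'
#' @param doc A document from a `lex_corpus`.
#' @return Two-column character matrix (`w1`, `w2`), zero rows for a
#'   single-token document.
#' @export
extract_bigrams <- function(doc) {
  stopifnot(inherits(doc, "lex_document"))
  toks <- doc$tokens
  L <- length(toks)
  if (L < 2L) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("w1", "w2"))))
  }
  cbind(w1 = toks[-L], w2 = toks[-1L])
}

#' Surprisal of a forward transitional probability
#'
#' `-log2(fwd_tp)`: the information, in bits, carried by the second word of
#' a bigram given the first. Zero iff the continuation is fully predictable.
#'
#' @param fwd_tp Probability in `(0, 1]`; vectorised.
#' @return Surprisal in bits (>= 0).
#' @examples
#' surprisal_bits(0.25)  # 2
#' @export
surprisal_bits <- function(fwd_tp) {
  if (any(fwd_tp <= 0 | fwd_tp > 1)) {
    stop("surprisal_bits(): fwd_tp must lie in (0, 1]", call. = FALSE)
  }
  -log2(fwd_tp)
}

#' Build the ranked bigram lexicon
#'
#' One entry per distinct adjacent pair, with raw frequency, contextual
#' diversity, deviation of proportions over per-document bigram counts,
#' frequency per million bigram tokens and its Zipf value, forward and
#' backward transitional probabilities, and surprisal. Transitional
#' probabilities use the words' total corpus frequencies as denominators
#' (`fwd = f(AB)/f(A)`, `bwd = f(AB)/f(B)`); a word's forward probabilities
#' therefore sum to slightly below 1 when it ends a document, by exactly its
#' document-final share. The bigram-token denominator for per-million
#' norming is `sum(L_d - 1)` over documents.
#'
#' @param corp A `lex_corpus`.
#' @param unigram_lexicon Lexicon built from the same corpus by
#'   [build_lexicon()].
#' @param tagger Optional tagger (see [stub_tagger()]); when given, entries
#'   are keyed by `(w1, pos1, w2, pos2)` and the output gains `pos1`,
#'   `pos2` columns.
#' @return Tibble `rank w1 w2 raw_freq n_texts dp fpm zipf fwd_tp bwd_tp
#'   surprisal` (plus `pos1`, `pos2` with a tagger), sorted by descending
#'   frequency with alphabetical tie-break.
#' @export
build_bigram_lexicon <- function(corp, unigram_lexicon, tagger = NULL) {
  stopifnot(inherits(corp, "lex_corpus"))
  sizes <- doc_lengths(corp)
  bigram_total <- sum(pmax(sizes - 1L, 0L))
  if (bigram_total == 0L) {
    stop("build_bigram_lexicon(): corpus contains no adjacent pairs",
         call. = FALSE)
  }

  per_doc <- lapply(corp$documents, function(d) {
    pairs <- extract_bigrams(d)
    if (nrow(pairs) == 0L) return(NULL)
    df <- tibble::tibble(w1 = pairs[, 1], w2 = pairs[, 2])
    if (!is.null(tagger)) {
      tg <- tagger(d$tokens)
      if (length(tg$pos) != length(d$tokens)) {
        stop("build_bigram_lexicon(): tagger returned wrong-length output",
             call. = FALSE)
      }
      df$pos1 <- tg$pos[-length(tg$pos)]
      df$pos2 <- tg$pos[-1L]
    }
    df$doc <- d$doc_id
    df
  })
  pairs <- dplyr::bind_rows(per_doc)
  keys <- if (is.null(tagger)) c("w1", "w2") else c("w1", "pos1", "w2", "pos2")

  by_doc <- pairs |>
    dplyr::count(dplyr::across(dplyr::all_of(c(keys, "doc"))),
                 name = "count")

  uni <- stats::setNames(unigram_lexicon$raw_freq, unigram_lexicon$wordform)
  missing_w <- setdiff(unique(c(pairs$w1, pairs$w2)), names(uni))
  if (length(missing_w) > 0L) {
    stop("build_bigram_lexicon(): words absent from the unigram lexicon: ",
         paste(utils::head(missing_w, 5), collapse = ", "), call. = FALSE)
  }

  # expected per-document shares of bigram tokens, for DP
  e_doc <- stats::setNames(pmax(sizes - 1L, 0L) / bigram_total,
                           names(corp$documents))

  entries <- by_doc |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      raw_freq = sum(count),
      n_texts = dplyr::n(),
      dp = {
        o <- count / sum(count)
        e <- e_doc[doc]
        (sum(abs(o - e) - e) + 1) / 2
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fpm = raw_freq / bigram_total * 1e6,
      zipf = zipf_value(fpm),
      fwd_tp = raw_freq / unname(uni[w1]),
      bwd_tp = raw_freq / unname(uni[w2]),
      surprisal = surprisal_bits(fwd_tp)
    ) |>
    dplyr::arrange(dplyr::desc(raw_freq),
                   dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  attr(entries, "bigram_total") <- bigram_total
  entries
}

#' Write a bigram lexicon to TSV
#'
#' Columns `rank w1 w2 raw_freq n_texts dp fpm zipf fwd_tp bwd_tp
#' surprisal`, plus `pos1 pos2` when present.
#'
#' @param bigrams Tibble from [build_bigram_lexicon()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bigrams_tsv <- function(bigrams, path) {
  cols <- c("rank", "w1", "w2", "raw_freq", "n_texts", "dp", "fpm", "zipf",
            "fwd_tp", "bwd_tp", "surprisal")
  if ("pos1" %in% names(bigrams)) cols <- c(cols, "pos1", "pos2")
  readr::write_tsv(bigrams[cols], path, progress = FALSE)
  invisible(path)
}
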