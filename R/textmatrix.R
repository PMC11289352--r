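#' Standardised type-token ratio (STTR)
#'
#' Divides the text into consecutive `chunk_size`-token parts, computes the
#' type-token ratio of each complete chunk and averages them; the final
#' partial chunk is discarded. A text shorter than one chunk falls back to
#' the whole-text TTR, so very short documents still receive a value.
#'
#' @param tokens Character vector of tokens.
#' @param chunk_size Tokens per chunk (default 100).
#' @return STTR in `(0, 1]`.
#' @export
sttr <- function(tokens, chunk_size = 100) {
  stopifnot(chunk_size >= 1)
  L <- length(tokens)
  if (L == 0L) stop("sttr(): empty token list", call. = FALSE)
  n_chunks <- L %/% chunk_size
  if (n_chunks == 0L) return(length(unique(tokens)) / L)
  ratios <- vapply(seq_len(n_chunks), function(k) {
    chunk <- tokens[((k - 1L) * chunk_size + 1L):(k * chunk_size)]
    length(unique(chunk)) / chunk_size
  }, numeric(1))
  mean(ratios)
}

#' Moving-average type-token ratio (MATTR)
#'
#' The mean type-token ratio over every contiguous window of `window`
#' tokens, the window advancing one token at a time. A text shorter than
#' one window falls back to the whole-text TTR.
#'
#' @param tokens Character vector of tokens.
#' @param window Window width in tokens (default 100).
#' @return MATTR in `(0, 1]`.
#' @export
mattr <- function(tokens, window = 100) {
  stopifnot(window >= 1)
  L <- length(tokens)
  if (L == 0L) stop("mattr(): empty token list", call. = FALSE)
  if (L < window) return(length(unique(tokens)) / L)
  ids <- match(tokens, unique(tokens))
  counts <- integer(max(ids))
  distinct <- 0L
  for (i in seq_len(window)) {
    counts[ids[i]] <- counts[ids[i]] + 1L
    if (counts[ids[i]] == 1L) distinct <- distinct + 1L
  }
  total <- distinct
  n_windows <- L - window + 1L
  if (n_windows > 1L) {
    for (start in 2L:n_windows) {
      out_id <- ids[start - 1L]
      counts[out_id] <- counts[out_id] - 1L
      if (counts[out_id] == 0L) distinct <- distinct - 1L
      in_id <- ids[start + window - 1L]
      counts[in_id] <- counts[in_id] + 1L
      if (counts[in_id] == 1L) distinct <- distinct + 1L
      total <- total + distinct
    }
  }
  total / n_windows / window
}

#' Per-document statistics
#'
#' Token count, type count, mean word length in characters, STTR, MATTR,
#' and — when a duration is attached — the input rate in words per minute
#' (`n_tokens / duration_min`).
#'
#' @param doc A document from a `lex_corpus`.
#' @param chunk_size STTR chunk size.
#' @param window MATTR window width.
#' @return One-row tibble with columns `doc_id`, `n_tokens`, `n_types`,
#'   `mean_word_len`, `sttr`, `mattr`, `duration_min`, `wpm`.
#' @export
doc_stats <- function(doc, chunk_size = 100, window = 100) {
  stopifnot(inherits(doc, "lex_document"))
  dur <- doc$duration_min
  if (!is.na(dur) && dur <= 0) {
    stop("doc_stats(): duration_min must be positive for '", doc$doc_id,
         "'", call. = FALSE)
  }
  toks <- doc$tokens
  tibble::tibble(
    doc_id = doc$doc_id,
    n_tokens = length(toks),
    n_types = length(unique(toks)),
    mean_word_len = mean(nchar(toks)),
    sttr = sttr(toks, chunk_size),
    mattr = mattr(toks, window),
    duration_min = dur,
    wpm = if (is.na(dur)) NA_real_ else length(toks) / dur
  )
}

#' Per-document statistics for a whole corpus
#'
#' @param corp A `lex_corpus`.
#' @inheritParams doc_stats
#' @return Tibble with one row per document, in corpus order.
#' @export
corpus_doc_stats <- function(corp, chunk_size = 100, window = 100) {
  stopifnot(inherits(corp, "lex_corpus"))
  dplyr::bind_rows(lapply(corp$documents, doc_stats,
                          chunk_size = chunk_size, window = window))
}

#' Summary statistics over documents
#'
#' Mean, sample SD (n - 1; reported as 0 with a note for a single
#' document), minimum and maximum of each per-document metric. Documents
#' without durations are excluded from the `duration_min` and `wpm` rows.
#'
#' @param stats Tibble from [corpus_doc_stats()] (or rows of
#'   [doc_stats()]).
#' @return Tibble `metric`, `mean`, `sd`, `min`, `max`, `n`.
#' @export
corpus_summary <- function(stats) {
  stopifnot(nrow(stats) >= 1L)
  metrics <- c("n_tokens", "n_types", "mean_word_len", "sttr", "mattr",
               "duration_min", "wpm")
  rows <- lapply(metrics, function(mcol) {
    v <- stats[[mcol]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      return(tibble::tibble(metric = mcol, mean = NA_real_, sd = NA_real_,
                            min = NA_real_, max = NA_real_, n = 0L))
    }
    s <- if (length(v) == 1L) 0 else stats::sd(v)
    if (length(v) == 1L) {
      message("corpus_summary(): single document; SD reported as 0 for ",
              mcol)
    }
    tibble::tibble(metric = mcol, mean = mean(v), sd = s,
                   min = min(v), max = max(v), n = length(v))
  })
  dplyr::bind_rows(rows)
}

#' Build the sparse document-term matrix
#'
#' A word per row and a document per column, cells holding token counts.
#' Rows follow lexicon rank order (descending frequency, alphabetical
#' tie-break); columns follow corpus document order. Row sums reproduce the
#' lexicon raw frequencies and column sums the document token counts.
#'
#' @param corp A `lex_corpus`.
#' @return A `Matrix::dgCMatrix` with dimnames.
#' @export
build_dtm <- function(corp) {
  stopifnot(inherits(corp, "lex_corpus"))
  X <- type_doc_matrix(corp)
  ord <- rank_order(Matrix::rowSums(X), rownames(X))
  X[ord, , drop = FALSE]
}

#' Write a DTM in Matrix Market coordinate format
#'
#' Writes `<basename>.mtx` plus sidecar label files `<basename>.rows.txt`
#' and `<basename>.cols.txt` (one label per line), the portable exchange
#' form for sparse count matrices.
#'
#' @param dtm A sparse matrix from [build_dtm()].
#' @param basename Output path without extension.
#' @return The `.mtx` path, invisibly.
#' @export
write_dtm <- function(dtm, basename) {
  mtx <- paste0(basename, ".mtx")
  Matrix::writeMM(dtm, mtx)
  writeLines(rownames(dtm), paste0(basename, ".rows.txt"), useBytes = TRUE)
  writeLines(colnames(dtm), paste0(basename, ".cols.txt"), useBytes = TRUE)
  invisible(mtx)
}

#' Read a DTM written by [write_dtm()]
#'
#' @param basename Path prefix used when writing.
#' @return A sparse matrix with row/column labels restored.
#' @export
read_dtm <- function(basename) {
  m <- methods::as(Matrix::readMM(paste0(basename, ".mtx")), "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(basename, ".rows.txt")),
                      readLines(paste0(basename, ".cols.txt")))
  m
}
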