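# Independent brute-force oracles and tiny corpus builders shared across
# the test files. The oracles deliberately avoid the package's internal
# code paths: plain table() counting and character-set bookkeeping.

toy_corpus <- function(...) {
  texts <- list(...)
  if (is.null(names(texts)) || any(!nzchar(names(texts)))) {
    names(texts) <- sprintf("doc%02d", seq_along(texts))
  }
  corpus(lapply(texts, function(s) strsplit(s, " ", fixed = TRUE)[[1]]))
}

random_small_corpus <- function(n_docs = 5, vocab = letters[1:8],
                                max_len = 40) {
  token_lists <- lapply(seq_len(n_docs), function(i) {
    sample(vocab, sample(3:max_len, 1), replace = TRUE)
  })
  names(token_lists) <- sprintf("d%02d", seq_len(n_docs))
  corpus(token_lists)
}

# unigram frequencies by one-pass counting over the concatenated tokens
oracle_unigram_counts <- function(corp) {
  tab <- table(unlist(lapply(corp$documents, `[[`, "tokens")))
  sort_idx <- order(-as.integer(tab), names(tab), method = "radix")
  data.frame(wordform = names(tab)[sort_idx],
             raw_freq = as.integer(tab)[sort_idx],
             stringsAsFactors = FALSE)
}

# bigram frequencies by pasting adjacent pairs per document
oracle_bigram_counts <- function(corp) {
  pair_keys <- unlist(lapply(corp$documents, function(d) {
    t <- d$tokens
    if (length(t) < 2) return(character(0))
    paste(t[-length(t)], t[-1], sep = "\r")
  }))
  table(pair_keys)
}

# replayed exposure oracle: consumes the RNG exactly as simulate_exposure()
# (full cds schedule then full book schedule per replicate, seed = base + r)
# but recounts the cumulative type union from scratch each day using raw
# character sets.
oracle_exposure <- function(cds_pool, book_pool, params) {
  days <- params$days
  types_mat <- matrix(0, days, params$reps)
  tokens_mat <- matrix(0, days, params$reps)
  cds_toks <- if (!is.null(cds_pool)) {
    lapply(cds_pool$documents, `[[`, "tokens")
  }
  book_toks <- if (!is.null(book_pool)) {
    lapply(book_pool$documents, `[[`, "tokens")
  }
  for (r in seq_len(params$reps)) {
    withr::with_seed(params$seed + r, {
      cds_draws <- if (params$transcripts_per_day > 0) {
        sample.int(length(cds_toks), days * params$transcripts_per_day,
                   replace = params$replacement)
      }
      book_draws <- if (params$books_per_day > 0) {
        sample.int(length(book_toks), days * params$books_per_day,
                   replace = params$replacement)
      }
      for (d in seq_len(days)) {
        day_docs <- c(
          if (!is.null(cds_draws)) {
            cds_toks[cds_draws[seq_len(d * params$transcripts_per_day)]]
          },
          if (!is.null(book_draws)) {
            book_toks[book_draws[seq_len(d * params$books_per_day)]]
          }
        )
        all_tokens <- unlist(day_docs, use.names = FALSE)
        types_mat[d, r] <- length(unique(all_tokens))
        tokens_mat[d, r] <- length(all_tokens)
      }
    })
  }
  list(mean_types = rowMeans(types_mat), mean_tokens = rowMeans(tokens_mat))
}
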