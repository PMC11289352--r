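#' Transcripts needed to approximate a daily token budget
#'
#' Converts a daily input figure in words to a whole number of transcripts,
#' given the mean transcript length, rounding half up with a minimum of
#' one. With a mean transcript length of 1737 tokens, daily budgets of
#' 8767, 17514 and 30142 words map to 5, 10 and 17 transcripts.
#'
#' @param tokens_per_day Daily word-input budget (> 0).
#' @param mean_transcript_len Mean transcript length in tokens (> 0).
#' @return Integer count of transcripts per day (>= 1).
#' @export
transcripts_per_day <- function(tokens_per_day, mean_transcript_len) {
  if (any(tokens_per_day <= 0) || any(mean_transcript_len <= 0)) {
    stop("transcripts_per_day(): inputs must be positive", call. = FALSE)
  }
  pmax(1L, as.integer(floor(tokens_per_day / mean_transcript_len + 0.5)))
}

#' Yearly token input from an hourly rate
#'
#' `words_per_hour * hours_per_day * days`, the convention behind
#' word-gap estimates built on a 14-hour waking day. Returns the exact
#' product; rounding to headline millions is left to the caller.
#'
#' @param words_per_hour Hourly input rate.
#' @param hours_per_day Waking hours per day (default 14).
#' @param days Days per year (default 365).
#' @return Token count.
#' @examples
#' yearly_tokens(2153)  # 11,001,830: about 11 million words a year
#' @export
yearly_tokens <- function(words_per_hour, hours_per_day = 14, days = 365) {
  stopifnot(words_per_hour > 0, hours_per_day > 0, days > 0)
  words_per_hour * hours_per_day * days
}

#' Daily shared-reading time for a books-per-day scenario
#'
#' `books_per_day * mean_book_minutes`: the time cost of a reading
#' scenario, e.g. three books a day at a mean reading time of 5.88 minutes
#' is about 18 minutes.
#'
#' @param books_per_day Books read per day (>= 0).
#' @param mean_book_minutes Mean reading time of one book, minutes.
#' @return Minutes per day.
#' @export
daily_reading_minutes <- function(books_per_day, mean_book_minutes) {
  stopifnot(books_per_day >= 0, mean_book_minutes > 0)
  books_per_day * mean_book_minutes
}

#' Parameters for an exposure simulation
#'
#' @param transcripts_per_day Child-directed-speech transcripts sampled
#'   each day (>= 0).
#' @param books_per_day Picture books sampled each day (>= 0). At least one
#'   of the two daily draws must be positive.
#' @param days Simulated days (default 365).
#' @param reps Monte-Carlo replicates averaged into the curve (default 30).
#' @param seed Base seed; replicate r runs under seed `seed + r` so the
#'   replicates are independent yet the experiment reproduces exactly.
#' @param replacement Sample documents with replacement across days
#'   (default `TRUE`). Without replacement, a replicate draws each document
#'   at most once and the pools must be large enough for
#'   `days * draws_per_day`.
#' @return An `exposure_params` object.
#' @export
exposure_params <- function(transcripts_per_day, books_per_day = 0,
                            days = 365, reps = 30, seed = 1,
                            replacement = TRUE) {
  stopifnot(transcripts_per_day >= 0, books_per_day >= 0,
            days >= 1, reps >= 1)
  if (transcripts_per_day == 0 && books_per_day == 0) {
    stop("exposure_params(): at least one daily draw must be positive",
         call. = FALSE)
  }
  structure(
    list(transcripts_per_day = as.integer(transcripts_per_day),
         books_per_day = as.integer(books_per_day),
         days = as.integer(days), reps = as.integer(reps),
         seed = as.integer(seed), replacement = isTRUE(replacement)),
    class = "exposure_params"
  )
}

# per-document type-index sets and token counts against a shared vocabulary
pool_profile <- function(corp, vocab) {
  list(
    types = lapply(doc_tokens(corp),
                   function(t) unique(match(t, vocab))),
    n_tokens = doc_lengths(corp),
    n_docs = corp$n_docs
  )
}

#' Simulate cumulative vocabulary-type exposure
#'
#' A hypothetical child hears `transcripts_per_day` transcripts drawn
#' uniformly at random from the child-directed-speech pool and
#' `books_per_day` books from the book pool, every day. Each replicate
#' keeps a cumulative set of the word types encountered and a running token
#' count; day d records the set size and token total after day d's draws.
#' The curve is the per-day mean over replicates, with per-replicate
#' trajectories retained for envelopes. Within a day draws are independent
#' (a document may repeat; repeats add tokens but no new types).
#'
#' @param cds_pool `lex_corpus` of transcripts (required when
#'   `transcripts_per_day > 0`).
#' @param book_pool `lex_corpus` of books, or `NULL` when
#'   `books_per_day = 0`.
#' @param params An [exposure_params()] object.
#' @return An `exposure_curve`: tibble `day`, `mean_cum_types`,
#'   `mean_cum_tokens`, `min_types`, `max_types`, with the full
#'   `days x reps` type/token trajectories in attributes `rep_types` and
#'   `rep_tokens`.
#' @export
simulate_exposure <- function(cds_pool, book_pool = NULL, params) {
  stopifnot(inherits(params, "exposure_params"))
  if (params$transcripts_per_day > 0 &&
      (is.null(cds_pool) || cds_pool$n_docs == 0L)) {
    stop("simulate_exposure(): transcripts_per_day > 0 needs a non-empty ",
         "cds_pool", call. = FALSE)
  }
  if (params$books_per_day > 0 &&
      (is.null(book_pool) || book_pool$n_docs == 0L)) {
    stop("simulate_exposure(): books_per_day > 0 needs a non-empty ",
         "book_pool", call. = FALSE)
  }

  vocab <- sort(unique(c(
    if (!is.null(cds_pool)) unlist(doc_tokens(cds_pool), use.names = FALSE),
    if (!is.null(book_pool)) unlist(doc_tokens(book_pool), use.names = FALSE)
  )), method = "radix")
  cds <- if (!is.null(cds_pool)) pool_profile(cds_pool, vocab)
  books <- if (!is.null(book_pool)) pool_profile(book_pool, vocab)

  days <- params$days
  rep_types <- matrix(0L, nrow = days, ncol = params$reps)
  rep_tokens <- matrix(0, nrow = days, ncol = params$reps)

  for (r in seq_len(params$reps)) {
    run <- withr::with_seed(params$seed + r, {
      draw_schedule <- function(pool, per_day) {
        if (per_day == 0L) return(NULL)
        total <- days * per_day
        if (params$replacement) {
          sample.int(pool$n_docs, total, replace = TRUE)
        } else {
          if (total > pool$n_docs) {
            stop("simulate_exposure(): without-replacement sampling needs ",
                 total, " documents but the pool has ", pool$n_docs,
                 call. = FALSE)
          }
          sample.int(pool$n_docs, total, replace = FALSE)
        }
      }
      cds_draws <- if (!is.null(cds)) draw_schedule(cds, params$transcripts_per_day)
      book_draws <- if (!is.null(books)) draw_schedule(books, params$books_per_day)

      seen <- logical(length(vocab))
      cum_types <- 0L
      cum_tokens <- 0
      types_day <- integer(days)
      tokens_day <- numeric(days)
      for (d in seq_len(days)) {
        absorb <- function(pool, draws, per_day) {
          if (per_day == 0L) return(invisible())
          idx <- draws[((d - 1L) * per_day + 1L):(d * per_day)]
          for (j in idx) {
            ts <- pool$types[[j]]
            new <- ts[!seen[ts]]
            if (length(new) > 0L) {
              seen[new] <<- TRUE
              cum_types <<- cum_types + length(new)
            }
            cum_tokens <<- cum_tokens + pool$n_tokens[[j]]
          }
        }
        absorb(cds, cds_draws, params$transcripts_per_day)
        absorb(books, book_draws, params$books_per_day)
        types_day[d] <- cum_types
        tokens_day[d] <- cum_tokens
      }
      list(types = types_day, tokens = tokens_day)
    })
    rep_types[, r] <- run$types
    rep_tokens[, r] <- run$tokens
  }

  curve <- tibble::tibble(
    day = seq_len(days),
    mean_cum_types = rowMeans(rep_types),
    mean_cum_tokens = rowMeans(rep_tokens),
    min_types = apply(rep_types, 1, min),
    max_types = apply(rep_types, 1, max)
  )
  attr(curve, "rep_types") <- rep_types
  attr(curve, "rep_tokens") <- rep_tokens
  attr(curve, "params") <- params
  class(curve) <- c("exposure_curve", class(curve))
  curve
}

#' Compare two exposure curves
#'
#' Per-day type difference and percentage gap between a baseline curve `a`
#' and a reference curve `b` (`gap = (types_b - types_a) / types_b * 100`),
#' plus the first day, if any, on which curve `a` reaches or exceeds curve
#' `b` — the day a reading intervention "closes the gap".
#'
#' @param curve_a,curve_b `exposure_curve` objects over the same day range.
#' @return Tibble `day`, `types_a`, `types_b`, `type_diff`, `gap_pct`, with
#'   attribute `first_crossing_day` (`NA` if `a` never reaches `b`).
#' @export
compare_curves <- function(curve_a, curve_b) {
  if (nrow(curve_a) != nrow(curve_b) ||
      !all(curve_a$day == curve_b$day)) {
    stop("compare_curves(): curves cover different day ranges",
         call. = FALSE)
  }
  out <- tibble::tibble(
    day = curve_a$day,
    types_a = curve_a$mean_cum_types,
    types_b = curve_b$mean_cum_types,
    type_diff = curve_b$mean_cum_types - curve_a$mean_cum_types,
    gap_pct = (curve_b$mean_cum_types - curve_a$mean_cum_types) /
      curve_b$mean_cum_types * 100
  )
  cross <- which(out$types_a >= out$types_b)
  attr(out, "first_crossing_day") <-
    if (length(cross) > 0L) out$day[cross[1]] else NA_integer_
  out
}

#' Write an exposure curve to TSV
#'
#' Columns `day mean_cum_types mean_cum_tokens min_types max_types`.
#'
#' @param curve An `exposure_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  readr::write_tsv(
    curve[c("day", "mean_cum_types", "mean_cum_tokens",
            "min_types", "max_types")],
    path, progress = FALSE
  )
  invisible(path)
}
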