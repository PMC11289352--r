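#' Default transcript-cleaning rules
#'
#' Automatic-speech-recognition captions carry non-speech annotations such as
#' `[Music]` or `[applause]`. The default rule set deletes exactly the
#' bracketed all-letter tags (case-insensitive) and nothing else; every other
#' character of the transcript is preserved.
#'
#' @param tag_patterns Character vector of Perl-compatible regular
#'   expressions to delete from raw transcripts.
#' @return An object of class `cleaning_rules`.
#' @examples
#' clean_transcript("a dog [Music] barked", cleaning_rules())
#' @export
cleaning_rules <- function(tag_patterns = "\\[[A-Za-z]+\\]") {
  stopifnot(is.character(tag_patterns), length(tag_patterns) >= 1L)
  structure(list(tag_patterns = tag_patterns), class = "cleaning_rules")
}

#' Remove annotation tags from a raw transcript
#'
#' Deletes every match of each pattern in `rules`; all remaining characters
#' (including the whitespace around deleted tags) are left untouched, so the
#' operation is idempotent.
#'
#' @param raw_text A length-1 character string (UTF-8).
#' @param rules A [cleaning_rules()] object.
#' @return The cleaned string.
#' @export
clean_transcript <- function(raw_text, rules = cleaning_rules()) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  if (!validUTF8(raw_text)) {
    stop("clean_transcript(): input is not valid UTF-8", call. = FALSE)
  }
  out <- raw_text
  for (pat in rules$tag_patterns) {
    out <- gsub(pat, "", out, perl = TRUE, ignore.case = TRUE)
  }
  out
}

#' Tokenise cleaned text into normalised wordforms
#'
#' Wordforms are lowercased. Apostrophes and hyphens are kept when internal
#' (contracted forms like `it's` and hyphenated words like `big-hearted` are
#' single tokens); every other punctuation character splits tokens. Leading
#' and trailing apostrophes/hyphens are stripped and empty strings are never
#' emitted. Curly apostrophes (U+2019) are normalised to ASCII `'` first, as
#' caption text mixes both. Digits are valid token characters: ASR output may
#' render spoken numbers as numerals.
#'
#' @param text A length-1 character string (already cleaned).
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("It's a big-hearted Dog!")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("’", "'", x, fixed = TRUE)
  # anything outside letters/digits/apostrophe/hyphen separates tokens
  x <- gsub("[^\\p{L}\\p{N}'-]+", " ", x, perl = TRUE)
  toks <- strsplit(trimws(x), "[ ]+")[[1]]
  toks <- gsub("^['-]+|['-]+$", "", toks)
  toks[nzchar(toks)]
}

new_document <- function(doc_id, tokens, title = NA_character_,
                         duration_min = NA_real_) {
  structure(
    list(doc_id = doc_id, tokens = tokens, title = title,
         duration_min = duration_min),
    class = "lex_document"
  )
}

#' Construct a corpus from token sequences
#'
#' A corpus is an ordered collection of documents, each a sequence of
#' normalised wordforms with an id and optional title/duration metadata.
#' Empty documents are rejected: no frequency norm is defined over zero
#' tokens.
#'
#' @param token_lists Named list of character vectors, one per document;
#'   names are the document ids.
#' @param titles Optional character vector (recycled NA) of titles.
#' @param durations_min Optional numeric vector of durations in minutes.
#' @return An object of class `lex_corpus` with elements `documents`,
#'   `n_docs`, `total_tokens`.
#' @examples
#' corpus(list(a = c("the", "cat"), b = c("the", "dog")))
#' @export
corpus <- function(token_lists, titles = NULL, durations_min = NULL) {
  stopifnot(is.list(token_lists), length(token_lists) >= 1L)
  ids <- names(token_lists)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop("corpus(): every document needs a non-empty id (list names)",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("corpus(): duplicate doc_ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  n <- length(token_lists)
  if (is.null(titles)) titles <- rep(NA_character_, n)
  if (is.null(durations_min)) durations_min <- rep(NA_real_, n)
  stopifnot(length(titles) == n, length(durations_min) == n)
  bad_dur <- !is.na(durations_min) & durations_min <= 0
  if (any(bad_dur)) {
    stop("corpus(): non-positive duration_min for: ",
         paste(ids[bad_dur], collapse = ", "), call. = FALSE)
  }
  docs <- vector("list", n)
  for (i in seq_len(n)) {
    toks <- token_lists[[i]]
    if (length(toks) == 0L) {
      stop("corpus(): document '", ids[i], "' has no tokens", call. = FALSE)
    }
    docs[[i]] <- new_document(ids[i], toks, titles[i], durations_min[i])
  }
  names(docs) <- ids
  structure(
    list(documents = docs, n_docs = n,
         total_tokens = sum(lengths(lapply(docs, `[[`, "tokens")))),
    class = "lex_corpus"
  )
}

#' @export
print.lex_corpus <- function(x, ...) {
  cat("<lex_corpus> ", x$n_docs, " documents, ", x$total_tokens,
      " tokens\n", sep = "")
  invisible(x)
}

doc_tokens <- function(corp) lapply(corp$documents, `[[`, "tokens")

doc_lengths <- function(corp) {
  vapply(corp$documents, function(d) length(d$tokens), integer(1))
}

read_txt_utf8 <- function(path, latin1_fallback = FALSE) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  txt <- rawToChar(raw)
  if (!validUTF8(txt)) {
    if (!latin1_fallback) {
      stop("load_corpus(): file is not valid UTF-8: ", path,
           " (set latin1_fallback = TRUE to re-decode permissively)",
           call. = FALSE)
    }
    txt <- iconv(txt, from = "latin1", to = "UTF-8")
  }
  Encoding(txt) <- "UTF-8"
  txt
}

#' Load a directory of plain-text transcripts as a corpus
#'
#' Reads every `.txt` file (one document per file, `doc_id` = file stem),
#' cleans it with `rules`, tokenises it, and assembles a corpus in
#' deterministic order (sorted by `doc_id`). Documents that are empty after
#' cleaning are dropped with a warning. An optional metadata table attaches
#' titles and durations; metadata rows whose `doc_id` matches no file are
#' ignored with a warning.
#'
#' @param input_dir Directory containing at least one readable `.txt` file.
#' @param metadata Optional data frame with columns `doc_id`, `title`,
#'   `duration_min`, or a path to a tab-separated file with that header.
#' @param rules A [cleaning_rules()] object.
#' @param latin1_fallback If `TRUE`, files that are not valid UTF-8 are
#'   re-decoded from Latin-1 instead of raising an error.
#' @return A `lex_corpus`.
#' @export
load_corpus <- function(input_dir, metadata = NULL,
                        rules = cleaning_rules(), latin1_fallback = FALSE) {
  stopifnot(dir.exists(input_dir))
  files <- list.files(input_dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("load_corpus(): no .txt files in ", input_dir, call. = FALSE)
  }
  stems <- sub("\\.txt$", "", basename(files))
  ord <- order(stems, method = "radix")
  files <- files[ord]; stems <- stems[ord]

  token_lists <- vector("list", length(files))
  for (i in seq_along(files)) {
    txt <- read_txt_utf8(files[i], latin1_fallback = latin1_fallback)
    token_lists[[i]] <- tokenize(clean_transcript(txt, rules))
  }
  names(token_lists) <- stems
  empty <- lengths(token_lists) == 0L
  if (any(empty)) {
    warning("load_corpus(): dropping ", sum(empty),
            " empty document(s) after cleaning: ",
            paste(stems[empty], collapse = ", "), call. = FALSE)
    token_lists <- token_lists[!empty]
    stems <- stems[!empty]
  }
  if (length(token_lists) == 0L) {
    stop("load_corpus(): all documents empty after cleaning", call. = FALSE)
  }

  titles <- rep(NA_character_, length(stems))
  durations <- rep(NA_real_, length(stems))
  if (!is.null(metadata)) {
    if (is.character(metadata) && length(metadata) == 1L) {
      metadata <- readr::read_tsv(metadata, show_col_types = FALSE,
                                  progress = FALSE)
    }
    metadata <- as.data.frame(metadata)
    stopifnot("doc_id" %in% names(metadata))
    unknown <- setdiff(metadata$doc_id, stems)
    if (length(unknown) > 0L) {
      warning("load_corpus(): metadata rows with no matching file ignored: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    idx <- match(stems, metadata$doc_id)
    if ("title" %in% names(metadata)) {
      titles <- as.character(metadata$title[idx])
    }
    if ("duration_min" %in% names(metadata)) {
      durations <- as.numeric(metadata$duration_min[idx])
    }
  }
  corpus(token_lists, titles = titles, durations_min = durations)
}

#' Write a corpus as a directory of text files
#'
#' One `.txt` file per document (tokens separated by spaces) plus, when any
#' document carries metadata, a `metadata.tsv` with header
#' `doc_id  title  duration_min`. The inverse of [load_corpus()] up to
#' whitespace.
#'
#' @param corp A `lex_corpus`.
#' @param out_dir Output directory (created if missing).
#' @param metadata Write the metadata sidecar? Default writes it whenever
#'   any duration or title is present.
#' @return `out_dir`, invisibly.
#' @export
write_corpus <- function(corp, out_dir, metadata = NULL) {
  stopifnot(inherits(corp, "lex_corpus"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in corp$documents) {
    writeLines(paste(d$tokens, collapse = " "),
               file.path(out_dir, paste0(d$doc_id, ".txt")), useBytes = TRUE)
  }
  titles <- vapply(corp$documents, `[[`, character(1), "title")
  durs <- vapply(corp$documents, `[[`, numeric(1), "duration_min")
  want_meta <- if (is.null(metadata)) any(!is.na(titles)) || any(!is.na(durs))
               else isTRUE(metadata)
  if (want_meta) {
    meta <- tibble::tibble(
      doc_id = names(corp$documents), title = titles, duration_min = durs
    )
    readr::write_tsv(meta, file.path(out_dir, "metadata.tsv"),
                     progress = FALSE)
  }
  invisible(out_dir)
}
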