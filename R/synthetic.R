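#' Configuration for the synthetic corpus generator
#'
#' Documents are bags of words drawn from a rank-frequency (Zipfian)
#' distribution `p(rank) ~ rank^-s` over a synthetic vocabulary
#' (`w0001`, `w0002`, ...). Document lengths are lognormal with the given
#' mean and SD on the token scale, clamped to `min_len` — children's book
#' corpora show strong right skew that a normal length model cannot
#' produce without negative lengths. When a words-per-minute distribution
#' is configured, durations are synthesised as `n_tokens / wpm`.
#'
#' Two presets mirror the corpora the simulator is aimed at:
#' `"books"` (picture-book-like: mean 522 tokens, SD 411, min 21, reading
#' rate 95 +/- 29 wpm) and `"cds"` (child-directed-speech-like transcripts:
#' mean 1737 tokens, SD 600, no durations).
#'
#' @param vocab_size Number of distinct types available (>= 2).
#' @param zipf_exponent Rank-frequency exponent s > 0.
#' @param n_docs Number of documents.
#' @param len_mean,len_sd Document length mean/SD in tokens.
#' @param min_len Minimum document length (>= 1, < `len_mean`).
#' @param wpm_mean,wpm_sd Optional words-per-minute distribution for
#'   duration synthesis (`NA` = no durations).
#' @param seed Integer seed; the whole corpus reproduces from it.
#' @param preset Optional `"books"` or `"cds"`; sets length/wpm fields,
#'   which explicit arguments then override.
#' @return A `synth_config` object.
#' @export
synth_config <- function(vocab_size = 5000, zipf_exponent = 1,
                         n_docs = 100, len_mean = 500, len_sd = 300,
                         min_len = 10, wpm_mean = NA_real_,
                         wpm_sd = NA_real_, seed = 1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("books", "cds"))
    defaults <- switch(preset,
      books = list(len_mean = 522, len_sd = 411, min_len = 21,
                   wpm_mean = 95, wpm_sd = 29),
      cds = list(len_mean = 1737, len_sd = 600, min_len = 50,
                 wpm_mean = NA_real_, wpm_sd = NA_real_)
    )
    supplied <- names(match.call())[-1]
    for (f in setdiff(names(defaults), supplied)) {
      assign(f, defaults[[f]])
    }
  }
  cfg <- list(vocab_size = as.integer(vocab_size),
              zipf_exponent = zipf_exponent, n_docs = as.integer(n_docs),
              len_mean = len_mean, len_sd = len_sd,
              min_len = as.integer(min_len),
              wpm_mean = wpm_mean, wpm_sd = wpm_sd,
              seed = as.integer(seed), preset = preset)
  if (cfg$vocab_size < 2L) {
    stop("synth_config(): vocab_size must be >= 2", call. = FALSE)
  }
  if (cfg$zipf_exponent <= 0) {
    stop("synth_config(): zipf_exponent must be > 0", call. = FALSE)
  }
  if (cfg$n_docs < 1L) {
    stop("synth_config(): n_docs must be >= 1", call. = FALSE)
  }
  if (cfg$min_len < 1L || cfg$len_mean <= cfg$min_len) {
    stop("synth_config(): need len_mean > min_len >= 1", call. = FALSE)
  }
  if (cfg$len_sd <= 0) {
    stop("synth_config(): len_sd must be > 0", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# lognormal (mu, sigma) matching a target mean and SD on the natural scale
lognormal_params <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Generate a seeded synthetic corpus
#'
#' Draws `n_docs` documents whose tokens are sampled independently from
#' the configured rank-frequency distribution; identical seeds give
#' byte-identical corpora. The generated corpus passes every corpus
#' invariant unchanged, so it can stand in for real transcript directories
#' in any pipeline function.
#'
#' @param config A [synth_config()] object.
#' @return A `lex_corpus` with documents `d0001`, `d0002`, ...
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  width_v <- max(4L, nchar(as.character(config$vocab_size)))
  vocab <- sprintf(paste0("w%0", width_v, "d"), seq_len(config$vocab_size))
  probs <- seq_len(config$vocab_size)^(-config$zipf_exponent)
  probs <- probs / sum(probs)
  lp <- lognormal_params(config$len_mean, config$len_sd)
  width_d <- max(4L, nchar(as.character(config$n_docs)))
  ids <- sprintf(paste0("d%0", width_d, "d"), seq_len(config$n_docs))
  have_wpm <- !is.na(config$wpm_mean) && !is.na(config$wpm_sd)

  withr::with_seed(config$seed, {
    lens <- pmax(config$min_len,
                 as.integer(round(stats::rlnorm(config$n_docs,
                                                lp$mu, lp$sigma))))
    token_lists <- lapply(lens, function(L) {
      vocab[sample.int(config$vocab_size, L, replace = TRUE, prob = probs)]
    })
    names(token_lists) <- ids
    durations <- NULL
    if (have_wpm) {
      wpm <- pmax(config$wpm_mean / 10,
                  stats::rnorm(config$n_docs, config$wpm_mean,
                               config$wpm_sd))
      durations <- lens / wpm
    }
    corpus(token_lists, durations_min = durations)
  })
}

#' Slope of the empirical rank-frequency law
#'
#' Ordinary least-squares slope of log10(frequency) on log10(rank) over a
#' lexicon — a quick fidelity check that generated corpora are roughly
#' Zipfian (slope near `-s`).
#'
#' @param lexicon A lexicon from [build_lexicon()].
#' @param max_rank Restrict the fit to the top ranks (default all).
#' @return The fitted slope (negative for Zipf-like data).
#' @export
zipf_slope <- function(lexicon, max_rank = nrow(lexicon)) {
  d <- lexicon[seq_len(min(max_rank, nrow(lexicon))), ]
  stats::coef(stats::lm(log10(raw_freq) ~ log10(rank), data = d))[[2]]
}
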