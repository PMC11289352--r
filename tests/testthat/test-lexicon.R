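test_that("Zipf values follow log10(per-million) + 3", {
  expect_equal(zipf_value(1), 3)
  expect_equal(zipf_value(1000), 6)
  expect_equal(zipf_value(raw_freq = 50, total_tokens = 5e5), 5)
  expect_error(zipf_value(0), "fpm")
  expect_error(zipf_value(-2), "fpm")
})

test_that("Laplace variant inflates by one per million and stays monotone", {
  expect_equal(zipf_value(0, laplace = TRUE), 3)
  expect_equal(zipf_value(9, laplace = TRUE), 4)
  fpms <- sort(runif(20, 0.01, 1e5))
  expect_true(all(diff(zipf_value(fpms)) > 0))
  expect_true(all(diff(zipf_value(fpms, laplace = TRUE)) > 0))
})

test_that("CoV is population SD over mean with max sqrt(n - 1)", {
  expect_equal(coefficient_of_variation(c(3, 3, 3, 3)), 0)
  expect_equal(coefficient_of_variation(c(1, 0, 0, 0, 0)), 2)  # sqrt(5 - 1)
  expect_equal(coefficient_of_variation(c(2, 4)), 1 / 3)
  expect_error(coefficient_of_variation(c(0, 0)), "all-zero")
})

test_that("DP is half the summed |observed - expected| proportions", {
  expect_equal(deviation_of_proportions(c(2, 2), c(100, 100)), 0)
  expect_equal(deviation_of_proportions(c(4, 0), c(100, 100)), 0.5)
  expect_equal(deviation_of_proportions(c(3, 1), c(150, 50)), 0)
  expect_error(deviation_of_proportions(c(1, 2), c(10, 10, 10)),
               "length mismatch")
})

test_that("a word confined to one of n equal documents attains the bounds", {
  for (n in c(2, 4, 7)) {
    counts <- c(5, rep(0, n - 1))
    sizes <- rep(100, n)
    expect_equal(deviation_of_proportions(counts, sizes), 1 - 1 / n)
    expect_equal(coefficient_of_variation(c(1, rep(0, n - 1))), sqrt(n - 1))
  }
})

test_that("the toy lexicon carries the exact norms", {
  cp <- toy_corpus(a = "the cat sat", b = "the dog")
  lx <- build_lexicon(cp)
  the <- lx[lx$wordform == "the", ]
  expect_equal(the$raw_freq, 2L)
  expect_equal(the$n_texts, 2L)
  expect_equal(the$fpm, 400000)
  expect_equal(the$zipf, log10(400000) + 3)
  singles <- lx[lx$wordform %in% c("cat", "dog", "sat"), ]
  expect_true(all(singles$raw_freq == 1L))
  expect_true(all(singles$n_texts == 1L))
  # descending frequency, alphabetical among ties
  expect_equal(lx$wordform, c("the", "cat", "dog", "sat"))
  expect_equal(lx$rank, 1:4)
})

test_that("a single-document corpus has DP = 0 and CoV = 0 throughout", {
  lx <- build_lexicon(toy_corpus(only = "b a a c b a"))
  expect_true(all(lx$dp == 0))
  expect_true(all(lx$cov == 0))
})

test_that("lexicon conserves tokens and per-million mass", {
  withr::with_seed(11, {
    for (i in 1:10) {
      cp <- random_small_corpus(n_docs = sample(2:6, 1))
      lx <- build_lexicon(cp)
      expect_identical(sum(lx$raw_freq), cp$total_tokens)
      expect_equal(sum(lx$fpm), 1e6, tolerance = 1e-6)
      expect_true(all(lx$dp >= 0 & lx$dp <= 1))
      expect_true(all(lx$cov >= 0 & lx$cov <= sqrt(cp$n_docs - 1) + 1e-12))
      expect_true(all(lx$n_texts >= 1 & lx$n_texts <= cp$n_docs))
    }
  })
})

test_that("lexicon frequencies match a naive counting oracle", {
  withr::with_seed(23, {
    for (i in 1:5) {
      cp <- random_small_corpus(n_docs = sample(3:8, 1), max_len = 120)
      stopifnot(cp$total_tokens <= 1000)
      lx <- build_lexicon(cp)
      orc <- oracle_unigram_counts(cp)
      expect_equal(lx$wordform, orc$wordform)
      expect_equal(lx$raw_freq, orc$raw_freq)
    }
  })
})

test_that("lexicon DP and CoV agree with the scalar formulas", {
  withr::with_seed(31, {
    cp <- random_small_corpus(n_docs = 6)
    lx <- build_lexicon(cp)
    dtm <- build_dtm(cp)
    sizes <- unname(Matrix::colSums(dtm))
    for (w in sample(lx$wordform, 5)) {
      counts <- as.numeric(dtm[w, ])
      row <- lx[lx$wordform == w, ]
      expect_equal(row$cov, coefficient_of_variation(counts))
      expect_equal(row$dp, deviation_of_proportions(counts, sizes))
    }
  })
})

test_that("tagged lexicon aggregates by (wordform, pos) and conserves mass", {
  cp <- toy_corpus(d = "a a b")
  tg <- build_tagged_lexicon(cp, stub_tagger())
  expect_equal(tg$raw_freq[tg$wordform == "a"], 2L)
  expect_equal(tg$raw_freq[tg$wordform == "b"], 1L)
  expect_true(all(tg$pos == "X"))
  expect_equal(tg$word_pos, c("a_X", "b_X"))

  lk <- data.frame(wordform = "cats", lemma = "cat", pos = "NNS")
  tg2 <- build_tagged_lexicon(toy_corpus(d = "cats cats"),
                              stub_tagger(lk))
  expect_equal(tg2$lemma, "cat")
  expect_equal(tg2$raw_freq, 2L)

  # per-wordform sums over tags equal the untagged raw frequencies
  withr::with_seed(5, cp3 <- random_small_corpus())
  tagger <- stub_tagger(data.frame(wordform = c("a", "b"),
                                   lemma = c("a", "b"),
                                   pos = c("NN", "VB")))
  tg3 <- build_tagged_lexicon(cp3, tagger)
  lx3 <- build_lexicon(cp3)
  sums <- tapply(tg3$raw_freq, tg3$wordform, sum)
  expect_equal(as.numeric(sums[lx3$wordform]), as.numeric(lx3$raw_freq))

  bad_tagger <- function(tokens) list(lemma = tokens[-1], pos = tokens[-1])
  expect_error(build_tagged_lexicon(cp, bad_tagger), "wrong-length")
})

test_that("high-frequency wordlists respect rank, ties and POS filters", {
  cp <- toy_corpus(a = "the cat sat", b = "the dog")
  lx <- build_lexicon(cp)
  expect_equal(top_n_wordlist(lx, 1), "the")
  expect_warning(all4 <- top_n_wordlist(lx, 10), "exceeds")
  expect_equal(all4, c("the", "cat", "dog", "sat"))

  tagger <- stub_tagger(data.frame(
    wordform = c("cat", "dog"), lemma = c("cat", "dog"),
    pos = c("NN", "NN")))
  tg <- build_tagged_lexicon(cp, tagger)
  nouns <- top_n_wordlist(lx, 2, pos_filter = c("NN", "NNS", "NNP"),
                          tagged = tg)
  expect_equal(nouns, c("cat", "dog"))
})

test_that("wordlist overlap reports membership and aligned ranks", {
  ten <- letters[1:10]
  same <- wordlist_overlap(ten, ten)
  expect_equal(same$n_shared, 10L)
  expect_length(same$absent_from_a, 0)
  expect_length(same$absent_from_b, 0)
  expect_equal(same$shared$rank_a, same$shared$rank_b)

  disj <- wordlist_overlap(letters[1:5], letters[6:10])
  expect_equal(disj$n_shared, 0L)

  part <- wordlist_overlap(c("x", "y", "z"), "y")
  expect_setequal(part$absent_from_b, c("x", "z"))
  expect_equal(part$n_shared + length(part$absent_from_b), 3L)
  expect_equal(part$shared$rank_a, 2L)
  expect_equal(part$shared$rank_b, 1L)

  expect_error(wordlist_overlap(c("a", "a"), "b"), "duplicates")
})

test_that("lexicon TSV export preserves the published columns", {
  lx <- build_lexicon(toy_corpus(a = "the cat sat", b = "the dog"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_tsv(lx, path)
  back <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  expect_equal(names(back), c("rank", "wordform", "raw_freq", "n_texts",
                              "fpm", "zipf", "cov", "dp"))
  expect_equal(back$raw_freq, lx$raw_freq)
  expect_equal(back$zipf, lx$zipf)
})
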