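---
title: "Corpus norms and exposure modelling with lexposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corpus norms and exposure modelling with lexposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexposure)
```

`lexposure` turns a directory of plain-text transcripts — typically
automatic captions of picture-book read-alouds, or child-directed-speech
transcripts — into the standard deliverables of a lexical-norm project: a
ranked wordform lexicon, a bigram lexicon with association statistics, a
per-document diversity table with a sparse document-term matrix, and a
Monte-Carlo model of how a child's cumulative vocabulary-type exposure
grows under daily speech-plus-book-reading scenarios. This vignette
explains the statistics, the assumptions behind them, and the design
choices made where conventions genuinely diverge.

## From raw text to a corpus

Cleaning removes caption metalanguage: the default rule deletes exactly
substrings of the form `[letters]` (case-insensitive), e.g. `[Music]`,
`[applause]`, and nothing else. Cleaning is idempotent, so re-running a
pipeline over already-cleaned text is harmless.

The tokeniser lowercases (so *The* and *the* are one type, the convention
of the SUBTLEX-family norms), keeps apostrophes and hyphens when internal
— contracted forms (*it's*) and hyphenated words (*big-hearted*) are
single tokens — and treats every other punctuation character as a
separator. Two decisions are worth flagging because caption text forced
them: curly apostrophes (U+2019) are folded to ASCII `'` before
tokenising, and digits are valid token characters, since speech
recognisers may emit `3` where a reader said *three*. Documents that are
empty after cleaning are dropped with a warning: no frequency norm is
defined over zero tokens. Files that are not valid UTF-8 raise an error
naming the file; `latin1_fallback = TRUE` re-decodes them permissively
instead. Systematic repair of mixed-encoding artefacts is out of scope —
inspect warnings and fix sources.

## The wordform lexicon

For each type, `build_lexicon()` reports raw frequency, contextual
diversity (`n_texts`, the number of documents containing the type),
frequency per million tokens, and three norms:

* **Zipf value** = `log10(frequency per million) + 3`, roughly a 1–7
  scale on large corpora. Toy corpora legitimately exceed 7: with 5
  tokens, a frequency of 2 is 400,000 per million. The Laplace variant
  (`laplace = TRUE`) computes `log10(fpm + 1) + 3`, reading the "+1 per
  million" inflation literally; it is **off** by default so that
  unattested forms are not imputed into a child's exposure.
* **CoV** = SD/mean of the type's counts across all corpus documents,
  zeros included. The SD is the *population* SD (divide by n): that is
  the convention under which the scale's stated maximum, `sqrt(n - 1)`,
  is attained exactly by a word confined to a single document — with a
  sample SD the bound would be violated, which is why population SD was
  chosen. The derivation for a single-document word with count c:
  mean `c/n`, population SD `c * sqrt(n - 1) / n`, ratio `sqrt(n - 1)`.
* **DP** (deviation of proportions) = `sum(|O - E|) / 2`, where `O` is
  the word's distribution over documents and `E` each document's share of
  corpus tokens. 0 means dispersion exactly proportional to document
  sizes; a single-document word in one of n equal documents scores
  `1 - 1/n`.

Ranks break frequency ties alphabetically so output is deterministic.
Conservation identities — raw frequencies summing to the corpus token
count, per-million frequencies summing to one million — are exact and
property-tested.

Lemmatisation and POS tagging are a pluggable interface, not a model: any
function mapping a token vector to equal-length lemma and tag vectors
plugs in. The shipped `stub_tagger()` is a deterministic lookup-table
tagger so that tagged lexicons, noun wordlists and POS-keyed bigrams are
testable with no external dependency; in production one would wrap a real
tagger behind the same contract.

## Document statistics and the document-term matrix

Because the plain type–token ratio falls mechanically with text length,
two normalised diversity measures are computed per document:

* **STTR** (chunked): mean TTR over consecutive complete 100-token
  chunks, the final partial chunk discarded. Texts shorter than one chunk
  fall back to the whole-text TTR — picture-book transcripts can be as
  short as ~21 tokens, so a fallback is unavoidable; it is reported on
  the same column rather than as missing.
* **MATTR** (moving window): mean TTR over all 100-token windows
  advancing one token at a time (the standard moving-average definition);
  same whole-text fallback below one window.

One subtlety uncovered while property-testing: MATTR is *not* monotone
under exact repetition of a text. Doubling a text halves its whole-text
TTR, but the `w - 1` windows spanning the seam between the two copies can
be more diverse than the within-text average, so MATTR can rise slightly.
The true bound, which the tests assert, is
`MATTR(2T) <= (2(L - w + 1) MATTR(T) + (w - 1)) / (2L - w + 1)`.

Input rate is `n_tokens / duration_min` (words per minute), computed
exactly from the duration supplied in metadata — no trimming of greetings
or asides is attempted, so rates are approximate for untrimmed videos.
Corpus-level summaries use the sample SD (n − 1), describing variability
across the observed documents; a single-document corpus reports SD 0 with
a note.

The document-term matrix is a `Matrix` sparse matrix, rows in lexicon
rank order and columns in corpus order, with row sums equal to lexicon
frequencies and column sums to document lengths (asserted exactly).
`write_dtm()` exports Matrix Market coordinate format plus one-label-per-
line sidecar files, readable from any scientific environment.

## The bigram lexicon

Bigrams are adjacent token pairs *within* a document; no pair crosses a
document boundary, and no sentence segmentation is attempted because
caption punctuation is unreliable. For a pair AB:

* forward TP = `f(AB) / f(A)`, backward TP = `f(AB) / f(B)`, with the
  denominators being the words' **total** corpus frequencies. Read
  literally this means a word's forward TPs sum to slightly under 1 when
  it ends documents; the deficit is exactly its document-final count over
  its frequency, and the tests assert that identity rather than hiding
  it.
* surprisal = `-log2(fwd TP)` bits; 0 iff the continuation is certain.
* bigram Zipf values are normalised per million *bigram* tokens, the
  denominator being `sum(L_d - 1)` over documents — the natural count of
  adjacent-pair events.
* DP for bigrams uses per-document bigram counts against each document's
  share of bigram tokens.

## The exposure simulator

`simulate_exposure()` models a hypothetical child who hears
`transcripts_per_day` transcripts and `books_per_day` books each day,
drawn uniformly at random from the respective pools. Each replicate keeps
a cumulative set of types encountered and a running token count; the
reported curve is the per-day mean over replicates (default 30), with
per-replicate trajectories kept for envelopes.

Key choices:

* **Sampling with replacement across days** is the default. A year-long
  high-input scenario draws on the order of the whole pool (e.g. 17
  transcripts × 365 days from a pool of a few thousand), so
  without-replacement sampling is fragile near exhaustion; it remains
  available as a switch (`replacement = FALSE`) and errors when the pool
  is too small rather than silently recycling.
* Within a day draws are independent: a document may repeat, adding
  tokens but no new types — consistent with cumulative-type bookkeeping.
* Replicate r runs under seed `seed + r`, so the experiment is exactly
  reproducible from one integer while replicates stay independent.
* `transcripts_per_day(tokens, mean_len)` rounds half-up with a floor of
  one; `yearly_tokens(rate)` returns the exact product
  `rate × hours × days` and leaves headline rounding to the caller, since
  published figures round inconsistently.
* `compare_curves()` reports the per-day type difference and the gap as
  `(types_b - types_a) / types_b × 100`, plus the first day the baseline
  is reached. The denominator convention is stated explicitly because
  published word-gap percentages are frequently not reconstructable from
  their own type counts; users comparing against external figures should
  check which denominator those figures used.

## The synthetic-corpus generator

`generate_corpus()` draws bag-of-words documents from a rank-frequency
law `p(rank) ∝ rank^(-s)` over a synthetic vocabulary, with lognormal
document lengths (children's book corpora are strongly right-skewed —
mean ≈ 522, SD ≈ 411, maxima near 5,000 tokens — which no normal length
model can produce without negative lengths) and optional durations
synthesised from a words-per-minute distribution. Two presets encode the
document profiles the simulator targets: `books` (length 522 ± 411
tokens, minimum 21, reading rate 95 ± 29 wpm) and `cds`
(child-directed-speech-like transcripts, 1737 ± 600 tokens, no
durations). The length SD of the cds preset is a modelling choice —
transcript-length dispersion is rarely published — as is the lognormal
form itself.

What the generator does *not* emulate, and what passing tests therefore
do not show: narrative structure, grammar, realistic bigram statistics
(documents are bags of words — bigram correctness is instead tested on
tiny hand-written documents with enumerable pair counts), age-banded
vocabulary, and mixed-encoding noise. Zipfian fidelity is checked
loosely: the log-log rank-frequency slope of a 10^5-token generated
corpus must lie within ±0.15 of −s.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run everything at desk scale,
chosen so the full suite completes in well under a minute of simulation
time: conservation laws over 50 generated corpora of 2–7 documents;
counting-oracle comparisons on corpora of at most 1,000 tokens; exposure
curves cross-checked against a brute-force recount at 20-document pools,
10 days, 5 replicates. The qualitative gap-closing experiment uses a
1,100-transcript pool (200 ± 70 tokens), a 400-book pool (80 ± 50
tokens), 100 days and 5 replicates, keeping the pool of the order of the
total number of draws — the regime the full-scale year model operates in.
In that experiment the book pool is generated with a flatter
rank-frequency exponent (0.8 vs 1.0) and a larger vocabulary than the
transcript pool, encoding the empirical contrast that picture books are
markedly more lexically diverse per token than child-directed speech;
without that contrast the book intervention cannot close a speech-input
gap at any scale, with it the three-books-a-day curve overtakes the
higher-input baseline well inside the simulated window.

## A worked miniature

```{r example}
cp <- corpus(list(a = c("the", "cat", "sat"), b = c("the", "dog")))
build_lexicon(cp)

bg <- build_bigram_lexicon(cp, build_lexicon(cp))
bg[, c("w1", "w2", "raw_freq", "fwd_tp", "surprisal")]
```

## Known limitations

* Norms computed from small corpora are noisy; Zipf values above 7 on toy
  corpora are arithmetic, not pathology.
* The tokeniser is a fixed policy, not a configurable grammar; languages
  with different clitic or compounding conventions need a different
  policy.
* The simulator models exposure, not learning: no repeated-reading
  effects, no Matthew effects, no caregiver vocabulary differences, and
  types are counted as encountered-once-or-not.
* Durations come from metadata as-is; words-per-minute rates inherit any
  untrimmed lead-in/lead-out time in those durations.
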