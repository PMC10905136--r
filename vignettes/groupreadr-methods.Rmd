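---
title: "Methods: emotional and semantic profiling of reading-group transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotional and semantic profiling of reading-group transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupreadr)
library(dplyr)
```

groupreadr quantifies what happens in shared-reading (group bibliotherapy)
discussions along two axes: the *emotional register* of the talk, measured
against human word-norm ratings, and its *semantic relationship* to the
literary text being discussed, measured with paragraph-vector document
embeddings. This vignette explains the models, the parameters that matter,
the synthetic-data generator used for validation, and the numerical
choices behind both.

## Emotional profiling with VAD word norms

The dimensional (VAD) model of affect describes every discrete emotion as
a combination of **valence** (pleasant–unpleasant), **arousal**
(stimulating–sedating) and **dominance** (in control–controlled). Word
norms are large corpora of words rated on these dimensions by human
participants on a 1–9 Likert scale; the best-known English set covers
about 14,000 common lemmas. Because norms exist for ordinary words, not
just overt mood vocabulary, they give a low-dimensional proxy for the
emotional register of any text.

`score_docs()` computes, for each document,

$$\bar v_{\text{doc}} = \frac{1}{n}\sum_{i=1}^{n} \frac{r(w_i) - 1}{8},$$

the mean rescaled norm value over all lemma *tokens* matched in the
lexicon (a lemma occurring $k$ times contributes $k$ observations — "all
the words of the text" is read as occurrences, not types). Ratings are
mapped affinely from the 1–9 scale onto $[0,1]$ so the three dimensions
are comparable. Three choices deserve emphasis:

* **Unmatched tokens are skipped, never imputed.** Imputing the scale
  midpoint would silently pull every document toward neutrality; instead
  the match rate is always reported as `coverage`.
* **Dispersion** is the word-level standard deviation within the
  document, sample ($n-1$) convention by default and population by
  option, since published summary tables rarely state which they used. A
  single matched token is given dispersion 0 under either convention.
* **Group ("term") averages** pool word tokens across a group's sessions
  by default, with an unweighted mean-of-session-means available by flag.
  With roughly equal session lengths the two agree closely; both are
  computed so neither convention is silently asserted.

`decile_tiers()` concatenates a group's transcripts into one corpus,
ranks the distinct matched lemma *types* by one dimension's value, and
cuts the ranking into ten tiers; the top and bottom tiers, carrying
corpus token frequencies, list the words most responsible for the high
and low ends of that dimension. Ranking is over types but frequencies
are over tokens, matching the frequency-sized word-cloud convention.
When two groups' same-end tiers are compared, `tiers_exclude_common()`
drops words present in both lists (they carry no contrast); a
within-group top-vs-bottom exclusion is also available. If every type
shares one value the split is degenerate and the function stops rather
than emitting arbitrary tiers.

"Emotional volatility" has two defensible operationalizations and
`volatility()` returns both: the within-session word-level SD, and the
session mean itself (e.g. low arousal = less energizing language). The
correlation layer uses the session mean by default and the SD by option.

## Semantic similarity with paragraph vectors

The package embeds documents with PV-DBOW (distributed bag of words
paragraph vectors), implemented in compiled code inside the package. Each
document $d$ carries a trainable vector $\mathbf d$; at every token
position a target word $w$ is sampled uniformly from the surrounding
context window and predicted from the document vector alone under the
negative-sampling objective

$$\mathcal L = -\log\sigma(\mathbf u_w \cdot \mathbf d)
  - \sum_{k=1}^{K}\log\sigma(-\mathbf u_{n_k} \cdot \mathbf d),$$

with negatives $n_k$ drawn from the unigram distribution raised to 0.75,
plain SGD and a linearly decaying learning rate. PV-DBOW is the simplest
paragraph-vector variant consistent with a window-plus-epochs
parameterisation; the window enters as the span from which targets are
sampled. Document similarity is the cosine of the trained vectors; an
affine map $s \mapsto (s+1)/2$ is available for display on a $[0,1]$
colour scale but raw cosine is the analysis default.

Parameters and defaults (`embed_config()`):

* `window` — a discourse specifier: large for dense, interdependent
  genres, small for strictly denotative ones. For conversation the
  package defaults to the rounded **mean sentence length of the group's
  discussions** (`sentence_stats()`), measured in raw tokens *before*
  stopword removal, because the window should reflect discourse span
  rather than post-filter token density.
* `epochs` — 30,000 by default, the stabilization point for corpora of a
  dozen short documents; desk-scale validation uses hundreds to a few
  thousand.
* `dim` 100, `negatives` 5, `min_count` 1 (the corpora are tiny),
  learning rate 0.025 → 0.0001.
* `seed` — a single master seed drives initialization, window sampling
  and negative sampling through a dedicated deterministic RNG; training
  is single-threaded with a fixed update order, so a (corpus, config)
  pair reproduces vectors bit-for-bit.

One model is trained per group (each group has its own window; its
sessions share vocabulary), with a joint model possible by passing both
groups' documents to `train_pvdbow()` yourself. Inference of unseen
documents is deliberately out of scope: every document of interest is in
the training set. Embedding similarity measures shared semantic content
only; it cannot identify *why* a discussion resembles a text (e.g.
character identification), and no such reading is attached to it.

## Cleaning

`tokenize()` removes bracketed stage directions (`[laughter]`; a flag
keeps them, since their analytic status is a judgement call), breaks on
hyphens and dashes, splits on whitespace, and strips edge punctuation
while keeping internal apostrophes. `clean_tokens()` lowercases,
normalizes curly apostrophes, drops punctuation-only tokens, lemmatizes
and removes stopwords (filtering both before and after lemmatization so
a function word cannot survive in either form). The lemmatizer is
pluggable: the bundled backend (dictionary of irregular forms plus
conservative plural rules, idempotent and total) is the default, so
results do not depend on an external model download; any function from
token vectors to lemma vectors can be substituted. The stopword list is
bundled and checksummed into run metadata because published analyses
rarely enumerate theirs; results are preprocessing-sensitive, which is
exactly why every resource is pinned and recorded.

## The synthetic study generator

`make_corpus()` generates a complete study with known ground truth: a
norm lexicon (values uniform or beta-shaped on 1–9), per-session literary
segments, multi-speaker discussions, and a feedback table, all written in
the same on-disk formats the readers consume. Its defaults *are* the
study conditions the package targets: two groups of six analysed
sessions, eight colour-coded speakers, Poisson sentence lengths with mean
12 tokens (typical conversational English), a 32-item 0–5 feedback
questionnaire with group sizes 9 and 7, and a planted group contrast —
the first group more on topic (text overlap 0.7 vs 0.4) and the second
with a slightly higher-valence, lower-arousal register.

Two planted signals make the pipeline testable end to end:

* **Topicality.** Each session owns a disjoint topic subvocabulary; its
  text is drawn from it, and each discussion token comes from it with
  probability `overlap`. Topic structure is a vocabulary partition, not a
  latent-topic model: it keeps the recovery oracle analytic while giving
  the embedder a real signal.
* **Register.** Discussion tokens are drawn with Gaussian kernel weights
  $\exp(-\lVert \mathbf{vad}(w) - \mathbf{target}\rVert^2 / 2\sigma^2)$
  around the group's target VAD point ($\sigma$ = `vad_noise`) — the
  stationary distribution of a per-token rejection sampler toward the
  target register, sampled directly for speed. Biasing the draw rather
  than relabelling norm values keeps lexicon and corpus consistent. A
  target with no lexicon support is an error, not a silent drift.

What the generator does *not* emulate matters for interpreting green
tests: synthetic words have no morphology, homonymy, syntax or discourse
structure; speakers have no styles and turn-taking is round-robin; topic
vocabularies are disjoint where real sessions of one book share
vocabulary heavily. Passing recovery tests therefore shows the pipeline
correctly extracts the signals it models — not that those signals
exhaust real reading-group talk, where preprocessing choices and lexicon
coverage add variance the generator does not contain.

## Statistics

The inferential layer is deliberately conventional: Pearson's $r$ with
the two-sided $t$-transform p-value for the similarity–emotion
correlations (sessions pooled across groups by default, since a single
coefficient per dimension implies pooling; per-group coefficients also
emitted), and independent-samples t-tests for group comparisons —
Student's equal-variance by default, the conventional reading at these
sample sizes, with Welch by flag and df always reported. Non-significant
correlations are reported numerically with an `ns` flag, never
suppressed. Per-item feedback tests apply no multiple-testing correction
by default (matching the raw-p convention of small pilot studies);
Benjamini–Hochberg adjustment is one flag away because 32 uncorrected
tests at $\alpha = .05$ is a known weakness. Degenerate constant-data
comparisons define $t = 0$, $p = 1$ when means agree rather than
erroring mid-pipeline.

## Numerical and design notes

* Decile cuts use rank-based tiling (`ntile`) after sorting by value and
  then lemma, so ties break deterministically; an all-tied dimension is
  an explicit error.
* Word output vectors initialize at zero and document vectors uniformly
  in $[-0.5, 0.5]/\text{dim}$, the word2vec-family convention; the
  log-sigmoid loss is computed with `log1p` in both branches for
  stability, and a non-finite epoch objective aborts training with the
  epoch named.
* Negative draws equal to the target are rejected and redrawn, so a
  two-type vocabulary is the minimum trainable corpus.
* Validation problem sizes were chosen to exercise each property at the
  smallest scale where the signal is unambiguous: gradient checks at
  dim 16; overlap-recovery at vocabulary 500, 12 sessions, dim 50,
  2,000 epochs over 20 seeds; end-to-end correlation recovery at
  vocabulary 300, dim 32, 600 epochs over 100 replicates; register
  recovery at vocabulary 5,000 with 5,000-token sessions.
* All of the package's randomness — generator and trainer — derives from
  explicit seeds; two runs from the same configuration are bit-identical
  (compared down to written CSV bytes in the test suite).

## A small worked example

```{r example}
cfg <- synth_config(seed = 42, n_groups = 2, sessions_per_group = 3,
                    vocab_size = 2000, topic_size = 40,
                    text_length = 200, discussion_length = 800,
                    feedback_items = 8)
corp <- make_corpus(cfg)
docs <- clean_corpus(corp$transcripts, corp$segments)
profiles <- score_docs(docs, corp$lexicon)
profiles |> filter(kind == "discussion") |>
  select(group_id, session, valence, arousal, dominance, coverage)

st <- sentence_stats(corp$transcripts)
models <- lapply(setNames(c("MT", "HT"), c("MT", "HT")), function(g) {
  w <- round(st$mean_sentence_length[st$group_id == g])
  train_pvdbow(docs[docs$group_id == g, ],
               embed_config(dim = 32, window = w, epochs = 800, seed = 42))
})
sims <- bind_rows(lapply(c("MT", "HT"), function(g) {
  text_discussion_similarity(models[[g]], docs[docs$group_id == g, ])$groups
}))
sims
```

The planted contrast (the MT generator used overlap 0.7, HT 0.4) should
be visible as a higher MT aggregate similarity. The same quantities at
full strength are recomputed by `scripts/acceptance.R`.

## Limitations

Lexicon-based scoring inherits the norms' blindness to homonymy, irony
and phrasal emotion; document means revert toward the language's
background register as documents grow; paragraph-vector similarity on a
dozen short documents is sensitive to hyperparameters (which is why every
run records them); and small-sample t-tests and correlations here
generate hypotheses rather than confirm them. The package surfaces all of
these rather than hiding them: coverage, dispersion, per-group results
and raw p-values are always reported alongside the headline numbers.
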