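# groupreadr

Quantitative analysis of shared-reading (group bibliotherapy) discussion
transcripts and the literary texts discussed in them. The package is for
researchers studying reading groups who record and transcribe the
discussion: it turns speaker-coded transcripts plus per-session literary
segments into (i) emotional profiles on the valence–arousal–dominance
(VAD) dimensional model of affect, (ii) document-embedding measures of
how closely each discussion tracks the text it responds to, and (iii)
the session-level statistics connecting the two.

## What it computes

**VAD emotional profiling.** Word norms rate ~14k English lemmas for
valence, arousal and dominance on a 1–9 scale. After cleaning
(tokenize → lemmatize → drop stopwords), each document's profile is the
mean rescaled value over matched lemma tokens,

&nbsp;&nbsp;&nbsp;&nbsp;*v̄* = (1/n) Σᵢ (r(wᵢ) − 1)/8 ∈ [0, 1],

with word-level SDs, lexicon coverage, per-session and pooled group
("term") summaries, and decile word tiers — the ranked word types
driving each end of each dimension, with corpus frequencies.

**Text–discussion similarity.** A PV-DBOW paragraph-vector model,
implemented in the package in compiled code, trains one vector per
document by predicting window-sampled words from the document vector
under a negative-sampling objective. The context window defaults to the
group's rounded mean sentence length; training is single-threaded and
seeded, so runs are bit-reproducible. Cosine similarity between a
session's discussion and its text measures how "on topic" the group was.

**Inference.** Pearson correlations between per-session similarity and
session emotion (the similarity–volatility question), Student/Welch
independent-samples t-tests comparing groups on per-session VAD and on
per-item 0–5 feedback questionnaires (raw p-values by default, optional
Benjamini–Hochberg).

**Synthetic studies.** `make_corpus()` generates complete seeded studies
(lexicon, segments, multi-speaker transcripts, feedback tables) with
known topical-overlap and emotional-register ground truth, in the exact
on-disk formats the readers parse — the basis of the package's
end-to-end validation.

## Worked example

```r
library(groupreadr)
library(dplyr)

cfg  <- synth_config(seed = 42, n_groups = 2, sessions_per_group = 3,
                     vocab_size = 2000, topic_size = 40,
                     text_length = 200, discussion_length = 800)
corp <- make_corpus(cfg)                      # seeded synthetic study
docs <- clean_corpus(corp$transcripts, corp$segments)

score_docs(docs, corp$lexicon) |>
  filter(kind == "discussion") |>
  select(group_id, session, valence, arousal, dominance, coverage)
#> # A tibble: 6 × 6
#>   group_id session valence arousal dominance coverage
#>   <chr>      <int>   <dbl>   <dbl>     <dbl>    <dbl>
#> 1 HT             1   0.682   0.389     0.585        1
#> 2 HT             2   0.554   0.421     0.581        1
#> 3 HT             3   0.650   0.396     0.582        1
#> 4 MT             1   0.579   0.475     0.514        1
#> 5 MT             2   0.576   0.435     0.487        1
#> 6 MT             3   0.614   0.519     0.635        1
```

The HT generator targeted a higher-valence, lower-arousal register
(0.62/0.39) than MT (0.55/0.45): the arousal means sit close to their
targets, and the group contrast in valence (HT 0.63 vs MT 0.59 averaged
over sessions) points the planted way, with per-session noise from each
session's small topic vocabulary. Coverage is 1 here because every
synthetic word is in the synthetic lexicon — on real transcripts it
reports the fraction of tokens the norms cover.

```r
st <- sentence_stats(corp$transcripts)        # window = mean sentence length
sims <- bind_rows(lapply(c("MT", "HT"), function(g) {
  m <- train_pvdbow(docs[docs$group_id == g, ],
                    embed_config(dim = 32, epochs = 800, seed = 42,
                                 window = round(
                                   st$mean_sentence_length[st$group_id == g])))
  text_discussion_similarity(m, docs[docs$group_id == g, ])$groups
}))
sims
#> # A tibble: 2 × 3
#>   group_id mean_similarity n_sessions
#>   <chr>              <dbl>      <int>
#> 1 MT                 0.400          3
#> 2 HT                 0.360          3
```

`mean_similarity` aggregates the cosine similarity between each
session's discussion vector and the vector of the text read in that
session. The MT generator drew 70% of discussion tokens from the session
text's topic vocabulary against HT's 40%, and the aggregate similarity
recovers that ordering.

Real studies run from files instead: `read_transcript()` /
`read_segment()` / `read_lexicon()` (Warriner-style CSV dialect by
default), or the whole pipeline at once via a YAML config and
`run_report()`, which writes every table (per-document profiles, group
summaries, tier word lists, similarity matrices, correlation and t-test
tables) plus run metadata with seeds and resource checksums. A
command-line wrapper ships in `inst/cli/groupreadr`:

```sh
Rscript inst/cli/groupreadr simulate --seed 7 --out study/
Rscript inst/cli/groupreadr report --config run.yaml
```

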