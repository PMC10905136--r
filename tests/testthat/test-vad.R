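test_that("rescaling maps the 1-9 scale onto [0,1] and validates input", {
  expect_identical(vad_rescale(1), 0)
  expect_identical(vad_rescale(9), 1)
  expect_identical(vad_rescale(5), 0.5)
  expect_error(vad_rescale(0.5), "outside")
  expect_error(vad_rescale(9.1), "outside")
  # strictly monotone
  x <- sort(runif(50, 1, 9))
  expect_true(all(diff(vad_rescale(x)) >= 0))
  expect_true(all(diff(vad_rescale(unique(x))) > 0))
})

test_that("document scoring means token occurrences, not types", {
  lex <- toy_lexicon(c("a", "b"), valence = c(5, 9))
  docs <- doc_tbl(c("a", "a", "b"))
  p <- score_docs(docs, lex)
  expect_equal(p$valence, (0.5 + 0.5 + 1.0) / 3, tolerance = 1e-12)
  expect_equal(p$n_scored, 3L)
  expect_equal(p$coverage, 1)

  one <- score_docs(doc_tbl(c("b")), lex)
  expect_equal(one$valence, 1.0)
  expect_equal(one$valence_sd, 0)
})

test_that("unmatched tokens are skipped and reported via coverage", {
  lex <- toy_lexicon(c("a", "b"), valence = c(5, 9))
  p <- score_docs(doc_tbl(c("a", "zzz", "b", "qqq")), lex)
  expect_equal(p$n_scored, 2L)
  expect_equal(p$coverage, 0.5)
  expect_equal(p$valence, 0.75)
  expect_error(score_docs(doc_tbl(c("zzz")), lex), "undefined")
})

test_that("scoring is a bag-of-words: order and duplication invariances", {
  set.seed(4)
  lex <- toy_lexicon(letters[1:10], valence = runif(10, 1, 9),
                     arousal = runif(10, 1, 9),
                     dominance = runif(10, 1, 9))
  doc <- sample(letters[1:10], 30, replace = TRUE)
  p1 <- score_docs(doc_tbl(doc), lex)
  p2 <- score_docs(doc_tbl(sample(doc)), lex)
  expect_equal(p1$valence, p2$valence)
  expect_equal(p1$arousal_sd, p2$arousal_sd)
  # doubling every token: mean unchanged, population sd unchanged
  pd <- score_docs(doc_tbl(rep(doc, each = 2)), lex,
                   sd_method = "population")
  pp <- score_docs(doc_tbl(doc), lex, sd_method = "population")
  expect_equal(pd$valence, pp$valence, tolerance = 1e-12)
  expect_equal(pd$valence_sd, pp$valence_sd, tolerance = 1e-12)
  # mean of rescaled equals rescaled mean of raw
  raw_mean <- mean(lex$valence[match(doc, lex$lemma)])
  expect_equal(pp$valence, (raw_mean - 1) / 8, tolerance = 1e-12)
})

test_that("group summary weights follow the chosen convention", {
  lex <- toy_lexicon(c("a", "b", "c", "d"), valence = c(1, 5, 5, 9))
  # two sessions, equal token counts, valence means 0.25 and 0.75
  docs <- doc_tbl(c("a", "b"), c("c", "d"))
  gs <- vad_group_summary(docs, lex)
  expect_equal(gs$term$mean[gs$term$dimension == "valence"], 0.5)
  expect_equal(nrow(gs$sessions), 2)
  # one session: term average equals the session average
  one <- vad_group_summary(doc_tbl(c("a", "b", "d")), lex)
  expect_equal(one$term$mean[one$term$dimension == "valence"],
               one$sessions$valence)
  # token pooling vs mean of session means differ with unequal lengths
  uneq <- doc_tbl(c("a", "a", "a", "b"), c("d", "b"))
  tok <- vad_group_summary(uneq, lex)$term
  ses <- vad_group_summary(uneq, lex, weighting = "session")$term
  vt <- tok$mean[tok$dimension == "valence"]
  vs <- ses$mean[ses$dimension == "valence"]
  expect_equal(vt, mean(c(0, 0, 0, 0.5, 1, 0.5)))
  expect_equal(vs, mean(c(mean(c(0, 0, 0, 0.5)), 0.75)))
})

test_that("group summary recovers the generator's target register", {
  cfg <- synth_config(seed = 21, n_groups = 1, sessions_per_group = 3,
                      vocab_size = 2000, topic_size = 60,
                      text_length = 100, discussion_length = 2500,
                      overlap = 0.2, vad_noise = 0.12,
                      vad_target = c(valence = 0.55, arousal = 0.45,
                                     dominance = 0.55))
  corp <- make_corpus(cfg)
  docs <- clean_corpus(corp$transcripts, corp$segments)
  gs <- vad_group_summary(docs, corp$lexicon)
  v <- gs$term$mean[gs$term$dimension == "valence"]
  expect_lt(abs(v - 0.55), 0.02)
})

test_that("decile tiers cut ranked types into tenths with frequencies", {
  vals <- seq(1.08, 9, length.out = 20) # rescaled 0.01..1 strictly increasing
  lex <- toy_lexicon(sprintf("t%02d", 1:20), valence = vals)
  # token frequencies: type i occurs i times
  doc <- rep(sprintf("t%02d", 1:20), times = 1:20)
  tiers <- decile_tiers(doc_tbl(doc), lex, "valence")
  bottom <- tiers[tiers$tier == "bottom", ]
  top <- tiers[tiers$tier == "top", ]
  expect_equal(bottom$lemma, c("t01", "t02"))
  expect_equal(top$lemma, c("t19", "t20"))
  expect_equal(top$frequency, c(19L, 20L))
  # partition property: values lie in their tier's range
  cut_low <- sort(vad_rescale(vals))[2]
  cut_high <- sort(vad_rescale(vals))[19]
  expect_true(all(bottom$value <= cut_low))
  expect_true(all(top$value >= cut_high))
})

test_that("degenerate and undersized tier inputs error", {
  lex_tied <- toy_lexicon(sprintf("t%02d", 1:12), valence = rep(5, 12))
  expect_error(decile_tiers(doc_tbl(sprintf("t%02d", 1:12)), lex_tied,
                            "valence"),
               "degenerate")
  lex <- toy_lexicon(letters[1:5], valence = 1:5 + 0.5)
  expect_error(decile_tiers(doc_tbl(letters[1:5]), lex, "valence"),
               "at least 10")
})

test_that("a planted high-valence subvocabulary dominates the top tier", {
  set.seed(7)
  n <- 100
  planted <- sprintf("hi%02d", 1:10)
  rest <- sprintf("lo%02d", 1:(n - 10))
  lex <- toy_lexicon(c(planted, rest),
                     valence = c(runif(10, 8.5, 9), runif(n - 10, 1, 7)))
  doc <- sample(c(rep(planted, 5), rep(rest, 2)))
  tiers <- decile_tiers(doc_tbl(doc), lex, "valence")
  top <- tiers$lemma[tiers$tier == "top"]
  expect_true(all(top %in% planted))
})

test_that("cross-group tier exclusion drops shared words from both lists", {
  a <- tibble::tibble(dimension = "valence",
                      tier = c("top", "top", "bottom"),
                      lemma = c("joy", "shared", "grim"),
                      value = c(0.9, 0.95, 0.1),
                      frequency = c(3L, 2L, 4L))
  b <- tibble::tibble(dimension = "valence",
                      tier = c("top", "bottom"),
                      lemma = c("shared", "dull"),
                      value = c(0.92, 0.15), frequency = c(5L, 1L))
  ex <- tiers_exclude_common(a, b)
  expect_false("shared" %in% ex$a$lemma)
  expect_false("shared" %in% ex$b$lemma)
  expect_true("joy" %in% ex$a$lemma)
  expect_true("dull" %in% ex$b$lemma)
})

test_that("volatility reports both dispersion operationalizations", {
  lex <- toy_lexicon(c("a", "b"), valence = c(1, 9))
  const <- score_docs(doc_tbl(c("a", "a", "a")), lex)
  expect_equal(volatility(const)$valence_sd, 0)
  both_pop <- score_docs(doc_tbl(c("a", "b")), lex,
                         sd_method = "population")
  expect_equal(both_pop$valence_sd, 0.5)
  both_smp <- score_docs(doc_tbl(c("a", "b")), lex)
  expect_equal(both_smp$valence_sd, sqrt(0.5), tolerance = 1e-12)
  one <- score_docs(doc_tbl(c("a")), lex)
  expect_error(volatility(one), "fewer than 2")
})
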