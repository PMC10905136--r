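test_that("tokenize splits on whitespace and strips punctuation edges", {
  expect_equal(tolower(tokenize("Yeah, fair point.")),
               c("yeah", "fair", "point"))
  expect_equal(tokenize(""), character(0))
  # em dash splits; stage direction removed; internal apostrophe kept
  expect_equal(tokenize("don’t—stop [laughter] now"),
               c("don’t", "stop", "now"))
  expect_equal(tokenize("one [pause] two", keep_stage_directions = TRUE),
               c("one", "pause", "two"))
  expect_equal(tokenize("well-known problem"), c("well", "known", "problem"))
})

test_that("cleaning lowercases, lemmatizes and drops stopwords in order", {
  dict <- c(cats = "cat", ran = "run")
  lem <- function(x) ifelse(x %in% names(dict), dict[x], x)
  out <- clean_tokens(c("The", "cats", "RAN"), lemmatizer = lem,
                      stopwords = "the")
  expect_equal(unname(out), c("cat", "run"))
  expect_equal(clean_tokens(c("the", "a", "an")), character(0))
  # punctuation-only tokens dropped even if tokenize let them through
  expect_equal(clean_tokens(c("...", "word")), "word")
})

test_that("cleaning is idempotent and never increases token count", {
  cfg <- synth_config(seed = 8, n_groups = 1, sessions_per_group = 1,
                      vocab_size = 50, topic_size = 10,
                      text_length = 60, discussion_length = 120)
  lex <- make_lexicon(cfg)
  s <- make_session(cfg, lex, "MT", 1)
  raw <- tokenize(paste(s$transcript$text, collapse = " "))
  english <- tokenize(paste(
    "The cats ran and ran [laughter] but we didn’t think",
    "they were really running towards the stories at all."))
  for (toks in list(raw, english)) {
    once <- clean_tokens(toks)
    twice <- clean_tokens(once)
    expect_equal(twice, once)
    expect_lte(length(once), length(toks))
    # deterministic
    expect_equal(clean_tokens(toks), once)
    expect_false(any(once %in% default_stopwords()))
  }
})

test_that("rule-based and dictionary-backend lemmatizers agree on a fixture", {
  # 50-token fixture whose inflected forms are all in the bundled
  # dictionary or regular plurals; the external-style backend is a pure
  # dictionary lookup configured with the same mappings
  fixture <- rep(c("cats", "ran", "stories", "children", "went", "boxes",
                   "said", "dogs", "leaves", "thought"), 5)
  dict <- c(default_lemma_dictionary(),
            cats = "cat", boxes = "box", dogs = "dog")
  external <- function(x) unname(ifelse(x %in% names(dict), dict[x], x))
  expect_equal(lemmatize(fixture, dictionary = dict), external(fixture))
})

test_that("sentence statistics average raw token counts per sentence", {
  tr <- tibble::tibble(group_id = "MT", session = 1L, index = 0L,
                       speaker = "GOLD",
                       text = "one two three four five six seven.")
  expect_equal(sentence_stats(tr)$mean_sentence_length, 7)

  tr2 <- tibble::tibble(group_id = "MT", session = 1L, index = 0:1,
                        speaker = "GOLD",
                        text = c("one two three four.", "a b c d e f!"))
  st2 <- sentence_stats(tr2)
  expect_equal(st2$mean_sentence_length, 5)
  expect_equal(st2$n_sentences, 2L)

  # stopwords are NOT removed before counting
  tr3 <- tibble::tibble(group_id = "MT", session = 1L, index = 0L,
                        speaker = "A1", text = "the cat sat on the mat.")
  expect_equal(sentence_stats(tr3)$mean_sentence_length, 6)

  expect_error(sentence_stats(tibble::tibble(group_id = "X", session = 1L,
                                             index = 0L, speaker = "A1",
                                             text = "")),
               "zero sentences")
})

test_that("generated sentence lengths recover the Poisson mean", {
  cfg <- synth_config(seed = 13, n_groups = 1, sessions_per_group = 1,
                      vocab_size = 100, topic_size = 10,
                      text_length = 50, discussion_length = 30000,
                      sentence_length_mean = 12)
  lex <- make_lexicon(cfg)
  s <- make_session(cfg, lex, "MT", 1)
  st <- sentence_stats(s$transcript)
  expect_gte(st$n_sentences, 2000)
  expect_lt(abs(st$mean_sentence_length - 12), 0.2)
})

test_that("clean_corpus builds one row per document with raw counts", {
  tr <- dplyr::bind_rows(
    read_transcript(write_lines_tmp(c("GOLD: The cats ran. [laughter]",
                                      "BLUE: Yeah, fair point.")),
                    "MT", 1),
    read_transcript(write_lines_tmp("RED: Something else entirely."),
                    "MT", 2))
  seg <- read_segment(write_lines_tmp(c("# T", "A story about cats.")),
                      "MT", 1)
  docs <- clean_corpus(tr, seg)
  expect_equal(nrow(docs), 3)
  expect_setequal(docs$kind, c("discussion", "text"))
  d1 <- docs$lemmas[[which(docs$session == 1 &
                             docs$kind == "discussion")]]
  expect_true(all(c("cat", "run", "yeah") %in% d1))
  expect_true(all(docs$n_raw_tokens >= lengths(docs$lemmas)))
})
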