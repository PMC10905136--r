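# shared fixture builders; everything is generated in code

# lexicon tibble on the raw 1-9 scale, as read_lexicon() returns
toy_lexicon <- function(lemma, valence, arousal = valence,
                        dominance = valence) {
  lex <- tibble::tibble(lemma = lemma, valence = valence,
                        arousal = arousal, dominance = dominance)
  attr(lex, "scale") <- c(1, 9)
  lex
}

# minimal document table compatible with score_docs()/train_pvdbow()
doc_tbl <- function(..., group_id = "MT", kind = "discussion") {
  lemmas <- list(...)
  tibble::tibble(
    group_id = group_id,
    session = seq_along(lemmas),
    kind = kind,
    doc_id = paste(group_id, seq_along(lemmas), kind, sep = "_"),
    lemmas = lemmas,
    n_raw_tokens = lengths(lemmas)
  )
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext,
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# independent brute-force VAD profile for one lemma vector: explicit loops,
# no dplyr, no package scoring path
brute_vad <- function(lemmas, lexicon, dim = "valence") {
  vals <- c()
  for (tok in lemmas) {
    i <- which(lexicon$lemma == tok)
    if (length(i) == 1) {
      vals <- c(vals, (lexicon[[dim]][i] - 1) / 8)
    }
  }
  n <- length(vals)
  m <- sum(vals) / n
  s <- if (n > 1) sqrt(sum((vals - m)^2) / (n - 1)) else 0
  list(mean = m, sd = s, n = n)
}
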