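#' Bundled English stopword list
#'
#' A fixed inventory of high-frequency function words removed during
#' cleaning. The list is bundled (and checksummed into run metadata) so
#' results do not depend on an external resource; pass `stopwords =` to
#' [clean_tokens()] to override it.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "groupreadr")
  readr::read_lines(path)
}

#' Bundled lemma dictionary
#'
#' Maps common irregular inflected forms (went, said, children, ...) to
#' their lemmas and pins exceptions to the plural-stripping rules. Used by
#' the rule-based fallback lemmatizer, the test default; an external
#' NLP-model lemmatizer can be plugged in via the `lemmatizer` argument of
#' [clean_tokens()].
#'
#' @return Named character vector: names are inflected forms, values
#'   lemmas.
#' @export
default_lemma_dictionary <- function() {
  path <- system.file("extdata", "lemmas_en.tsv", package = "groupreadr")
  tab <- readr::read_tsv(path, col_names = c("form", "lemma"),
                         show_col_types = FALSE, progress = FALSE)
  stats::setNames(tab$lemma, tab$form)
}

#' Tokenize raw text
#'
#' Splits on whitespace after removing bracketed stage directions (e.g.
#' `[laughter]`, `[pause]`) and breaking on hyphens/en-/em-dashes, then
#' strips leading and trailing punctuation from each chunk. Internal
#' apostrophes are kept (`don't` stays one token). Case is preserved;
#' case-folding happens in [clean_tokens()].
#'
#' @param text Character scalar (or vector; results are concatenated per
#'   element into one list).
#' @param keep_stage_directions If `TRUE`, bracketed directions are kept as
#'   ordinary text rather than removed.
#' @return Character vector of raw tokens (empty for empty input).
#' @export
#' @examples
#' tokenize("Yeah, fair point.")
tokenize <- function(text, keep_stage_directions = FALSE) {
  if (length(text) == 0L) return(character(0))
  text <- paste(text, collapse = " ")
  if (!keep_stage_directions) {
    text <- stringr::str_remove_all(text, "\\[[^\\]]*\\]")
  }
  # hyphen, en dash, em dash, horizontal bar split tokens
  text <- stringr::str_replace_all(text, "[-‐‑‒–—―]+", " ")
  chunks <- stringr::str_split_1(stringr::str_trim(text), "\\s+")
  toks <- stringr::str_remove_all(chunks, "^[^\\p{L}\\p{N}]+|[^\\p{L}\\p{N}]+$")
  toks[nzchar(toks)]
}

#' Rule-based fallback lemmatizer
#'
#' Dictionary lookup first, then conservative plural stripping:
#' `-ies -> -y`, `-es` after sibilants dropped, a final `-s` dropped unless
#' the word ends in `-ss`, `-us` or `-is`. Unknown forms are returned
#' unchanged, so the function is total, and dictionary values are their own
#' lemmas, so it is idempotent.
#'
#' @param tokens Character vector of lowercase tokens.
#' @param dictionary Named character vector of form -> lemma overrides.
#' @return Character vector of lemmas, same length as `tokens`.
#' @export
lemmatize <- function(tokens, dictionary = default_lemma_dictionary()) {
  out <- tokens
  hit <- out %in% names(dictionary)
  out[hit] <- unname(dictionary[out[hit]])
  rest <- !hit
  n <- nchar(out)
  ies <- rest & n > 4 & stringr::str_ends(out, "ies")
  out[ies] <- paste0(stringr::str_sub(out[ies], 1, -4), "y")
  rest <- rest & !ies
  sib <- rest & n > 3 &
    stringr::str_detect(out, "(ses|xes|zes|ches|shes)$")
  out[sib] <- stringr::str_sub(out[sib], 1, -3)
  rest <- rest & !sib
  plain <- rest & n > 3 & stringr::str_ends(out, "s") &
    !stringr::str_detect(out, "(ss|us|is|'s)$")
  out[plain] <- stringr::str_sub(out[plain], 1, -2)
  out
}

#' Clean raw tokens into lemma sequences
#'
#' Applies the cleaning pipeline: case-folding, punctuation-token removal,
#' lemmatization and stopword removal, preserving token order. Stopwords
#' are filtered both before and after lemmatization so that an inflected
#' function word cannot survive via its lemma or vice versa. Curly
#' apostrophes are normalized to straight ones during case-folding.
#'
#' @param tokens Character vector of raw tokens from [tokenize()].
#' @param lemmatizer Function mapping a character vector of lowercase
#'   tokens to lemmas; must be total (identity on unknown forms). Defaults
#'   to the bundled rule-based [lemmatize()].
#' @param stopwords Character vector of stopwords to drop.
#' @return Character vector of cleaned lowercase lemmas.
#' @export
#' @examples
#' clean_tokens(tokenize("The cats RAN home."))
clean_tokens <- function(tokens, lemmatizer = lemmatize,
                         stopwords = default_stopwords()) {
  if (length(tokens) == 0L) return(character(0))
  x <- tolower(tokens)
  x <- stringr::str_replace_all(x, "[’‘]", "'")
  x <- x[stringr::str_detect(x, "[\\p{L}\\p{N}]")]
  x <- x[!x %in% stopwords]
  x <- lemmatizer(x)
  x <- x[!x %in% stopwords]
  x[nzchar(x) & !stringr::str_detect(x, "\\s")]
}

#' Clean a corpus of transcripts and literary segments
#'
#' Builds the document table the scoring and embedding stages consume: one
#' row per document (a session's discussion or the literary segment read in
#' it) with its cleaned lemma sequence.
#'
#' @param transcripts Tibble of utterances as returned by
#'   [read_transcript()] (rows from several sessions/groups may be bound
#'   together).
#' @param segments Tibble of literary segments from [read_segment()], or
#'   `NULL`.
#' @inheritParams clean_tokens
#' @inheritParams tokenize
#' @return A tibble with columns `group_id`, `session`, `kind`
#'   (`"discussion"` or `"text"`), `doc_id`, `lemmas` (list column),
#'   `n_raw_tokens`.
#' @export
clean_corpus <- function(transcripts, segments = NULL,
                         lemmatizer = lemmatize,
                         stopwords = default_stopwords(),
                         keep_stage_directions = FALSE) {
  disc <- transcripts |>
    dplyr::group_by(.data$group_id, .data$session) |>
    dplyr::summarise(raw = list(tokenize(.data$text,
                                         keep_stage_directions)),
                     .groups = "drop") |>
    dplyr::mutate(kind = "discussion")
  docs <- disc
  if (!is.null(segments) && nrow(segments) > 0) {
    seg <- segments |>
      dplyr::group_by(.data$group_id, .data$session) |>
      dplyr::summarise(raw = list(tokenize(.data$text,
                                           keep_stage_directions)),
                       .groups = "drop") |>
      dplyr::mutate(kind = "text")
    docs <- dplyr::bind_rows(docs, seg)
  }
  docs |>
    dplyr::mutate(
      doc_id = paste(.data$group_id, .data$session, .data$kind, sep = "_"),
      n_raw_tokens = purrr::map_int(.data$raw, length),
      lemmas = purrr::map(.data$raw, clean_tokens, lemmatizer = lemmatizer,
                          stopwords = stopwords)
    ) |>
    dplyr::select("group_id", "session", "kind", "doc_id", "lemmas",
                  "n_raw_tokens") |>
    dplyr::arrange(.data$group_id, .data$session, .data$kind)
}

#' Per-group mean sentence length
#'
#' Sentences are delimited by terminal punctuation (`.`, `!`, `?`) or the
#' end of an utterance; length is counted in raw tokens before stopword
#' removal, because the embedding window should reflect discourse span
#' rather than post-filter density. The rounded group mean is the default
#' context window of the paragraph-vector model.
#'
#' @param transcripts Utterance tibble from [read_transcript()].
#' @return A tibble with one row per group: `group_id`,
#'   `mean_sentence_length`, `n_sentences`.
#' @export
sentence_stats <- function(transcripts) {
  res <- transcripts |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(lens = list(sentence_lengths(.data$text)),
                     .groups = "drop") |>
    dplyr::mutate(
      n_sentences = purrr::map_int(.data$lens, length),
      mean_sentence_length = purrr::map_dbl(.data$lens, mean)
    ) |>
    dplyr::select("group_id", "mean_sentence_length", "n_sentences")
  if (any(res$n_sentences == 0L)) {
    stop("group(s) with zero sentences: ",
         paste(res$group_id[res$n_sentences == 0L], collapse = ", "),
         call. = FALSE)
  }
  res
}

# token counts of the sentences in a vector of utterance texts
sentence_lengths <- function(texts) {
  pieces <- unlist(stringr::str_split(texts, "[.!?]+"))
  lens <- vapply(pieces, function(p) length(tokenize(p)), integer(1),
                 USE.NAMES = FALSE)
  lens[lens > 0L]
}
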