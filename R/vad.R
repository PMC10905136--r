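#' Rescale a raw word-norm rating to the unit interval
#'
#' Ratings collected on a bounded Likert scale (1-9 for the published VAD
#' norms) are mapped affinely to `[0, 1]`, `(raw - min) / (max - min)`, so
#' the three dimensions are directly comparable.
#'
#' @param raw Numeric vector of raw ratings.
#' @param scale Numeric `c(min, max)` of the source scale.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' vad_rescale(c(1, 5, 9))
vad_rescale <- function(raw, scale = c(1, 9)) {
  if (any(is.na(raw)) || any(raw < scale[1]) || any(raw > scale[2])) {
    stop("raw rating(s) outside [", scale[1], ", ", scale[2], "]",
         call. = FALSE)
  }
  (raw - scale[1]) / (scale[2] - scale[1])
}

# long tibble of rescaled per-token values: doc rows x matched tokens,
# columns doc_id/group_id/session/kind/lemma/valence/arousal/dominance
scored_tokens <- function(docs, lexicon) {
  scale <- attr(lexicon, "scale") %||% c(1, 9)
  lex01 <- dplyr::mutate(
    lexicon,
    valence = vad_rescale(.data$valence, scale),
    arousal = vad_rescale(.data$arousal, scale),
    dominance = vad_rescale(.data$dominance, scale)
  )
  docs |>
    dplyr::select("group_id", "session", "kind", "doc_id", "lemmas") |>
    tidyr::unnest_longer("lemmas", values_to = "lemma") |>
    dplyr::inner_join(lex01, by = "lemma")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single observation has zero dispersion under either convention
sd_fun <- function(sd_method) {
  switch(match.arg(sd_method, c("sample", "population")),
    sample = function(x) if (length(x) < 2) 0 else stats::sd(x),
    population = function(x) sqrt(mean((x - mean(x))^2))
  )
}

#' Score documents on the VAD dimensions
#'
#' The emotional profile of a document is the mean (and dispersion) of the
#' rescaled valence, arousal and dominance norms over all its lemma tokens
#' matched in the lexicon: a lemma occurring k times contributes k
#' observations. Unmatched tokens are skipped, never imputed at the scale
#' midpoint, and the match rate is reported as `coverage`.
#'
#' @param docs Document tibble from [clean_corpus()] (columns `doc_id`,
#'   `lemmas`, ...).
#' @param lexicon Norm lexicon from [read_lexicon()] (raw 1-9 values).
#' @param sd_method `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @return A tibble with one row per document: id columns plus
#'   `valence`, `arousal`, `dominance` (means in `[0, 1]`), `valence_sd`,
#'   `arousal_sd`, `dominance_sd` (word-level dispersion), `n_scored`,
#'   `n_tokens`, `coverage`.
#' @export
score_docs <- function(docs, lexicon, sd_method = "sample") {
  sdf <- sd_fun(sd_method)
  toks <- scored_tokens(docs, lexicon)
  prof <- toks |>
    dplyr::group_by(.data$group_id, .data$session, .data$kind,
                    .data$doc_id) |>
    dplyr::summarise(
      dplyr::across(c("valence", "arousal", "dominance"),
                    list(mean = mean, sd = sdf)),
      n_scored = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::rename(valence = "valence_mean", arousal = "arousal_mean",
                  dominance = "dominance_mean")
  missing <- setdiff(docs$doc_id, prof$doc_id)
  if (length(missing)) {
    stop("no lexicon-matched tokens in document(s): ",
         paste(missing, collapse = ", "), " - VAD profile undefined",
         call. = FALSE)
  }
  docs |>
    dplyr::transmute(.data$doc_id,
                     n_tokens = purrr::map_int(.data$lemmas, length)) |>
    dplyr::right_join(prof, by = "doc_id") |>
    dplyr::mutate(coverage = .data$n_scored / .data$n_tokens) |>
    dplyr::select("group_id", "session", "kind", "doc_id",
                  "valence", "arousal", "dominance",
                  "valence_sd", "arousal_sd", "dominance_sd",
                  "n_scored", "n_tokens", "coverage")
}

#' Group-level VAD summary table
#'
#' Produces, per group and dimension, the term average (pooled over all the
#' group's matched word tokens across sessions, the default weighting) with
#' its word-level SD, alongside the per-session profile rows. A
#' mean-of-session-means weighting is available because published summary
#' tables do not always state which convention they use.
#'
#' @inheritParams score_docs
#' @param kind Which documents to summarise (`"discussion"` default).
#' @param weighting `"token"` (pool word tokens across sessions, default)
#'   or `"session"` (unweighted mean of session means).
#' @return A list with two tibbles: `term` (one row per group x dimension:
#'   `group_id`, `dimension`, `mean`, `sd`, `n_tokens`) and `sessions`
#'   (per-session profiles from [score_docs()]).
#' @export
vad_group_summary <- function(docs, lexicon, kind = "discussion",
                              weighting = c("token", "session"),
                              sd_method = "sample") {
  weighting <- match.arg(weighting)
  sdf <- sd_fun(sd_method)
  use <- docs[docs$kind == kind, ]
  if (nrow(use) == 0L) stop("no documents of kind '", kind, "'",
                            call. = FALSE)
  sessions <- score_docs(use, lexicon, sd_method = sd_method)
  if (weighting == "token") {
    term <- scored_tokens(use, lexicon) |>
      tidyr::pivot_longer(c("valence", "arousal", "dominance"),
                          names_to = "dimension", values_to = "value") |>
      dplyr::group_by(.data$group_id, .data$dimension) |>
      dplyr::summarise(mean = mean(.data$value), sd = sdf(.data$value),
                       n_tokens = dplyr::n(), .groups = "drop")
  } else {
    term <- sessions |>
      tidyr::pivot_longer(c("valence", "arousal", "dominance"),
                          names_to = "dimension", values_to = "value") |>
      dplyr::group_by(.data$group_id, .data$dimension) |>
      dplyr::summarise(mean = mean(.data$value), sd = sdf(.data$value),
                       n_tokens = sum(.data$n_scored), .groups = "drop")
  }
  term <- dplyr::mutate(term, dimension = factor(
    .data$dimension, levels = c("valence", "arousal", "dominance"))) |>
    dplyr::arrange(.data$group_id, .data$dimension)
  list(term = term, sessions = sessions)
}

#' Decile word tiers per emotion dimension
#'
#' Concatenates a group's documents into one corpus, ranks the distinct
#' lexicon-matched lemma types by their value on one VAD dimension, cuts
#' the ranking into ten equal tiers, and reports the top and bottom tiers
#' with corpus token frequencies — the words most responsible for the high
#' and low end of that dimension in the group's talk.
#'
#' @inheritParams score_docs
#' @param dimension One of `"valence"`, `"arousal"`, `"dominance"`.
#' @param exclude `"none"` (default) or `"within"`: drop lemmas appearing
#'   in both the top and bottom tier of this report (possible only in the
#'   degenerate tied case). For the cross-group exclusion used when
#'   comparing two groups' clouds, see [tiers_exclude_common()].
#' @param n_tiers Number of tiers (10 for deciles).
#' @return A tibble with columns `dimension`, `tier` (`"bottom"`/`"top"`),
#'   `lemma`, `value` (rescaled norm), `frequency` (corpus token count),
#'   ordered by extremity.
#' @export
decile_tiers <- function(docs, lexicon, dimension = "valence",
                         exclude = c("none", "within"), n_tiers = 10) {
  dimension <- match.arg(dimension, c("valence", "arousal", "dominance"))
  exclude <- match.arg(exclude)
  toks <- scored_tokens(docs, lexicon)
  types <- toks |>
    dplyr::count(.data$lemma, name = "frequency") |>
    dplyr::left_join(
      dplyr::distinct(toks, .data$lemma, value = .data[[dimension]]),
      by = "lemma"
    )
  if (nrow(types) < n_tiers) {
    stop("need at least ", n_tiers, " distinct matched lemma types, got ",
         nrow(types), call. = FALSE)
  }
  if (dplyr::n_distinct(types$value) == 1L) {
    stop("all matched types share one ", dimension,
         " value; tiers are degenerate", call. = FALSE)
  }
  ranked <- types |>
    dplyr::arrange(.data$value, .data$lemma) |>
    dplyr::mutate(tier_no = dplyr::ntile(dplyr::row_number(), n_tiers))
  out <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(ranked, .data$tier_no == 1L),
                  tier = "bottom"),
    dplyr::mutate(dplyr::filter(ranked, .data$tier_no == n_tiers),
                  tier = "top")
  )
  if (exclude == "within") {
    both <- intersect(out$lemma[out$tier == "top"],
                      out$lemma[out$tier == "bottom"])
    out <- out[!out$lemma %in% both, ]
  }
  out |>
    dplyr::mutate(dimension = dimension) |>
    dplyr::arrange(.data$tier, .data$value) |>
    dplyr::select("dimension", "tier", "lemma", "value", "frequency")
}

#' Drop words common to two groups' same tier
#'
#' When two groups' top (or bottom) tier word lists are compared, words
#' present in both carry no contrast, so they are excluded from both
#' reports.
#'
#' @param a,b Tier reports from [decile_tiers()] for the two groups.
#' @return A list of the two filtered reports, `list(a = , b = )`.
#' @export
tiers_exclude_common <- function(a, b) {
  drop_common <- function(x, y) {
    keep <- !purrr::map2_lgl(x$lemma, x$tier, function(l, t) {
      l %in% y$lemma[y$tier == t]
    })
    x[keep, ]
  }
  list(a = drop_common(a, b), b = drop_common(b, a))
}

#' Emotional volatility measures
#'
#' Two operationalizations of how emotionally volatile a session is, both
#' reported: the word-level dispersion of the norm values inside the
#' session (`*_sd`) and the session-level mean itself (the quantity the
#' similarity correlation uses by default — e.g. "the lower the arousal").
#'
#' @param profiles Per-document profile tibble from [score_docs()].
#' @return `profiles` with only the id, mean and sd columns, i.e. a
#'   session-level volatility table.
#' @export
volatility <- function(profiles) {
  if (any(profiles$n_scored < 2)) {
    stop("word-level sd undefined for document(s) with fewer than 2 ",
         "scored tokens", call. = FALSE)
  }
  dplyr::select(profiles, "group_id", "session", "kind", "doc_id",
                "valence", "arousal", "dominance",
                "valence_sd", "arousal_sd", "dominance_sd")
}
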