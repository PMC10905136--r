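colour_codes <- c("GOLD", "YELLOW", "BLUE", "RED", "GREEN", "SILVER",
                  "PURPLE", "ORANGE", "PINK", "BROWN", "GREY", "WHITE")

#' Synthetic reading-group study configuration
#'
#' Defines the generating conditions for a synthetic shared-reading study
#' with known ground truth: a VAD norm lexicon, one literary segment and
#' one multi-speaker discussion per session, and a post-participation
#' feedback table. Defaults emulate the structure of a two-term study:
#' two groups of six analysed sessions, colour-coded speakers, a 32-item
#' feedback questionnaire scored 0-5 with group sizes 9 and 7, and
#' conversational sentence lengths (mean 12 tokens). The first group is
#' generated more "on topic" (higher text overlap) and the second with a
#' slightly higher-valence, lower-arousal register, so the pipeline's
#' group contrasts have a known direction.
#'
#' @param seed Master seed; all generator streams derive from it.
#' @param n_groups,sessions_per_group Study shape.
#' @param vocab_size Lexicon size (>= 20).
#' @param topic_size Session topic subvocabulary size, in types.
#' @param text_length,discussion_length Token counts per literary segment
#'   and per discussion.
#' @param overlap Fraction of discussion tokens drawn from the session
#'   text's topic subvocabulary; scalar or named per-group vector.
#' @param vad_target Named vector `c(valence=, arousal=, dominance=)` in
#'   `[0, 1]`, or a list of such vectors named by group.
#' @param vad_noise SD of the word-value kernel around `vad_target`.
#' @param vad_shapes List of `c(shape1, shape2)` beta parameters per
#'   dimension for the lexicon's raw value distributions (default
#'   uniform).
#' @param n_speakers Speakers per discussion (<= 12; colour pseudonyms).
#' @param sentence_length_mean Poisson mean of sentence lengths in tokens.
#' @param feedback_items Number of questionnaire items.
#' @param feedback_n Integer vector of participants per group.
#' @param planted_item_effects Named numeric: mean shifts (in score units)
#'   added to the first group for the named items, e.g. `c("5" = 1.5)`.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_groups = 2, sessions_per_group = 6,
                         vocab_size = 500, topic_size = 30,
                         text_length = 300, discussion_length = 600,
                         overlap = c(MT = 0.7, HT = 0.4),
                         vad_target = list(
                           MT = c(valence = 0.55, arousal = 0.45,
                                  dominance = 0.55),
                           HT = c(valence = 0.62, arousal = 0.39,
                                  dominance = 0.59)),
                         vad_noise = 0.1,
                         vad_shapes = list(valence = c(1, 1),
                                           arousal = c(1, 1),
                                           dominance = c(1, 1)),
                         n_speakers = 8, sentence_length_mean = 12,
                         feedback_items = 32, feedback_n = c(9, 7),
                         planted_item_effects = numeric(0)) {
  stopifnot(vocab_size >= 20, topic_size >= 5, text_length > 0,
            discussion_length > 0, vad_noise > 0,
            n_speakers >= 1, n_speakers <= length(colour_codes),
            sentence_length_mean > 1, feedback_items >= 1,
            length(feedback_n) >= 1)
  stopifnot(all(unlist(overlap) >= 0), all(unlist(overlap) <= 1))
  fields <- as.list(environment())
  structure(fields, class = "synth_config")
}

group_ids <- function(config) {
  ids <- c("MT", "HT")
  if (config$n_groups <= 2) return(ids[seq_len(config$n_groups)])
  c(ids, paste0("G", seq(3, config$n_groups)))
}

config_overlap <- function(config, group) {
  ov <- config$overlap
  if (length(ov) == 1 && is.null(names(ov))) return(unname(unlist(ov)))
  ov <- unlist(ov)
  if (!group %in% names(ov)) return(unname(ov[[1]]))
  unname(ov[[group]])
}

config_target <- function(config, group) {
  vt <- config$vad_target
  if (is.list(vt)) {
    vt <- if (group %in% names(vt)) vt[[group]] else vt[[1]]
  }
  norm_target(vt)
}

norm_target <- function(vt) {
  if (is.null(names(vt))) names(vt) <- c("valence", "arousal", "dominance")
  stopifnot(all(c("valence", "arousal", "dominance") %in% names(vt)),
            all(vt >= 0), all(vt <= 1))
  vt
}

derived_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587)
}

#' Generate a synthetic VAD norm lexicon
#'
#' Lemmas `w0001 ... wN` with raw 1-9 valence/arousal/dominance values
#' drawn from configurable beta shapes (uniform by default), in the same
#' tibble format as [read_lexicon()]. Deterministic under the config seed.
#'
#' @param config A [synth_config()].
#' @return Lexicon tibble (`lemma`, `valence`, `arousal`, `dominance`)
#'   with attribute `scale = c(1, 9)`.
#' @export
make_lexicon <- function(config) {
  set.seed(derived_seed(config$seed, 1))
  V <- config$vocab_size
  draw <- function(sh) 1 + 8 * stats::rbeta(V, sh[1], sh[2])
  lex <- tibble::tibble(
    lemma = sprintf("w%05d", seq_len(V)),
    valence = draw(config$vad_shapes$valence),
    arousal = draw(config$vad_shapes$arousal),
    dominance = draw(config$vad_shapes$dominance)
  )
  attr(lex, "scale") <- c(1, 9)
  lex
}

# deterministic, disjoint topic subvocabulary for one (group, session)
topic_words <- function(config, lexicon, group_index, session) {
  k <- config$topic_size
  slot <- (group_index - 1) * config$sessions_per_group + (session - 1)
  lo <- (slot * k) %% nrow(lexicon) + 1
  idx <- ((lo - 1 + seq_len(k) - 1) %% nrow(lexicon)) + 1
  lexicon$lemma[idx]
}

# Gaussian kernel weights of lexicon words around a VAD target; the
# stationary distribution of per-token rejection sampling toward the
# target register
vad_weights <- function(lexicon, vad_target, vad_noise) {
  v <- vad_rescale(lexicon$valence)
  a <- vad_rescale(lexicon$arousal)
  d <- vad_rescale(lexicon$dominance)
  d2 <- (v - vad_target[["valence"]])^2 + (a - vad_target[["arousal"]])^2 +
    (d - vad_target[["dominance"]])^2
  w <- exp(-d2 / (2 * vad_noise^2))
  if (!any(w > 1e-12)) {
    stop("infeasible vad_target: no lexicon word near (",
         paste(round(vad_target, 2), collapse = ", "), ") at noise ",
         vad_noise, call. = FALSE)
  }
  w
}

#' Generate one synthetic session
#'
#' Draws a literary segment from a session-specific topic subvocabulary,
#' then a discussion whose tokens come from that subvocabulary with
#' probability `overlap` and otherwise from the rest of the lexicon, in
#' both cases weighted toward the group's target VAD register
#' (Gaussian kernel of width `vad_noise` around `vad_target`). Tokens are
#' arranged into Poisson-length sentences and round-robin speaker turns.
#'
#' @param config A [synth_config()].
#' @param lexicon Lexicon from [make_lexicon()].
#' @param group Group label (must match [group_ids] of the config).
#' @param session 1-based session number.
#' @param overlap,vad_target Optional overrides of the config values for
#'   this session.
#' @return List with `segment` (one-row tibble), `transcript` (utterance
#'   tibble) and `truth` (list: `overlap`, `vad_target`, `topic_words`).
#' @export
make_session <- function(config, lexicon, group, session,
                         overlap = NULL, vad_target = NULL) {
  gid <- group_ids(config)
  gi <- match(group, gid)
  if (is.na(gi)) stop("unknown group: ", group, call. = FALSE)
  overlap <- overlap %||% config_overlap(config, group)
  vad_target <- norm_target(vad_target %||% config_target(config, group))
  set.seed(derived_seed(config$seed, 1000 * gi + session))

  topic <- topic_words(config, lexicon, gi, session)
  in_topic <- lexicon$lemma %in% topic
  w_all <- vad_weights(lexicon, vad_target, config$vad_noise)
  w_topic <- w_all[in_topic]
  w_bg <- w_all[!in_topic]
  if (!any(w_topic > 1e-12) || !any(w_bg > 1e-12)) {
    stop("infeasible vad_target for this session's vocabulary pools",
         call. = FALSE)
  }

  text_toks <- sample(topic, config$text_length, replace = TRUE)
  from_topic <- stats::runif(config$discussion_length) < overlap
  n_t <- sum(from_topic)
  disc_toks <- character(config$discussion_length)
  if (n_t > 0) {
    disc_toks[from_topic] <- sample(topic, n_t, replace = TRUE,
                                    prob = w_topic)
  }
  if (n_t < config$discussion_length) {
    disc_toks[!from_topic] <- sample(lexicon$lemma[!in_topic],
                                     config$discussion_length - n_t,
                                     replace = TRUE, prob = w_bg)
  }

  seg_text <- paste(to_sentences(text_toks, config$sentence_length_mean),
                    collapse = " ")
  sentences <- to_sentences(disc_toks, config$sentence_length_mean)
  speakers <- colour_codes[seq_len(config$n_speakers)]
  transcript <- tibble::tibble(
    group_id = group, session = as.integer(session),
    index = seq_along(sentences) - 1L,
    speaker = rep_len(speakers, length(sentences)),
    text = sentences
  )
  segment <- tibble::tibble(group_id = group, session = as.integer(session),
                            title = paste0("Segment ", group, "-S", session),
                            text = seg_text)
  list(segment = segment, transcript = transcript,
       truth = list(overlap = overlap, vad_target = vad_target,
                    topic_words = topic))
}

# split a token stream into period-terminated sentences with
# Poisson(lambda) lengths (>= 1 token)
to_sentences <- function(tokens, lambda) {
  n <- length(tokens)
  lens <- integer(0)
  while (sum(lens) < n) {
    more <- pmax(1L, stats::rpois(16, lambda))
    lens <- c(lens, more)
  }
  cut <- cumsum(lens)
  k <- which(cut >= n)[1]
  lens <- lens[seq_len(k)]
  lens[k] <- lens[k] - (cut[k] - n)
  lens <- lens[lens > 0L]
  stop_at <- cumsum(lens)
  start_at <- c(1L, head(stop_at, -1) + 1L)
  vapply(seq_along(lens), function(i) {
    paste0(paste(tokens[start_at[i]:stop_at[i]], collapse = " "), ".")
  }, character(1))
}

#' Generate a synthetic feedback score table
#'
#' Integer scores 0-5 per participant and item around a common mean, with
#' optional planted mean shifts on designated items in the first group.
#'
#' @param config A [synth_config()].
#' @param base_mean,base_sd Latent score distribution before rounding and
#'   clamping to the 0-5 scale.
#' @return Tibble (`participant`, `group_id`, `item`, `score`).
#' @export
make_feedback <- function(config, base_mean = 3, base_sd = 1) {
  set.seed(derived_seed(config$seed, 999983))
  gid <- group_ids(config)
  ns <- rep_len(config$feedback_n, config$n_groups)
  shifts <- config$planted_item_effects
  purrr::map_dfr(seq_along(gid), function(gi) {
    purrr::map_dfr(seq_len(ns[gi]), function(p) {
      mu <- rep(base_mean, config$feedback_items)
      if (gi == 1 && length(shifts)) {
        it <- as.integer(names(shifts))
        mu[it] <- mu[it] + unname(shifts)
      }
      score <- pmin(5, pmax(0, round(stats::rnorm(config$feedback_items,
                                                  mu, base_sd))))
      tibble::tibble(participant = sprintf("%s_P%02d", gid[gi], p),
                     group_id = gid[gi],
                     item = seq_len(config$feedback_items),
                     score = as.numeric(score))
    })
  })
}

#' Generate a full synthetic study
#'
#' Lexicon, every session of every group, and the feedback table; if `dir`
#' is given, everything is also written in the exact on-disk formats the
#' readers consume (speaker-prefixed transcript text files, segment text
#' files, lexicon CSV, feedback CSV) plus a `ground_truth.json`.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory.
#' @param overlaps,vad_targets Optional per-session overrides: tibbles /
#'   lists keyed by `(group_id, session)`; see [make_session()]. Each may
#'   be a function `(group, session) -> value` for programmatic designs.
#' @return List: `lexicon`, `transcripts` (all utterances), `segments`,
#'   `feedback`, `truth` (tibble: `group_id`, `session`, `overlap`,
#'   `valence_target`, `arousal_target`, `dominance_target`), `config`.
#' @export
make_corpus <- function(config = synth_config(), dir = NULL,
                        overlaps = NULL, vad_targets = NULL) {
  lexicon <- make_lexicon(config)
  gid <- group_ids(config)
  sessions <- tidyr::expand_grid(group_id = gid,
                                 session = seq_len(config$sessions_per_group))
  parts <- purrr::pmap(sessions, function(group_id, session) {
    ov <- if (is.function(overlaps)) overlaps(group_id, session) else NULL
    vt <- if (is.function(vad_targets)) vad_targets(group_id, session)
          else NULL
    make_session(config, lexicon, group_id, session,
                 overlap = ov, vad_target = vt)
  })
  transcripts <- purrr::map_dfr(parts, "transcript")
  segments <- purrr::map_dfr(parts, "segment")
  truth <- purrr::map2_dfr(purrr::map(parts, "truth"),
                           seq_len(nrow(sessions)), function(tr, i) {
    tibble::tibble(group_id = sessions$group_id[i],
                   session = sessions$session[i],
                   overlap = tr$overlap,
                   valence_target = tr$vad_target[["valence"]],
                   arousal_target = tr$vad_target[["arousal"]],
                   dominance_target = tr$vad_target[["dominance"]])
  })
  feedback <- make_feedback(config)
  out <- list(lexicon = lexicon, transcripts = transcripts,
              segments = segments, feedback = feedback, truth = truth,
              config = config)
  if (!is.null(dir)) write_synth_corpus(out, dir)
  out
}

write_synth_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "transcripts"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "segments"), showWarnings = FALSE)
  corpus$transcripts |>
    dplyr::group_split(.data$group_id, .data$session) |>
    purrr::walk(function(df) {
      path <- file.path(dir, "transcripts",
                        sprintf("%s_s%02d.txt", df$group_id[1],
                                df$session[1]))
      readr::write_lines(paste0(df$speaker, ": ", df$text), path)
    })
  purrr::pwalk(corpus$segments, function(group_id, session, title, text) {
    path <- file.path(dir, "segments",
                      sprintf("%s_s%02d.txt", group_id, session))
    readr::write_lines(c(paste("#", title), text), path)
  })
  write_table(corpus$lexicon, file.path(dir, "lexicon.csv"))
  write_table(corpus$feedback, file.path(dir, "feedback.csv"))
  jsonlite::write_json(corpus$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
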