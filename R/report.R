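#' Read a pipeline run configuration
#'
#' YAML with blocks `paths` (`transcripts`, `segments`, `lexicon`,
#' `feedback` (optional), `out`), `preprocess`
#' (`keep_stage_directions`), `embed` (any [embed_config()] field;
#' `window: auto` uses the per-group rounded mean sentence length),
#' `stats` (`measure`, `equal_var`, `adjust`) and a top-level `seed`.
#'
#' @param path YAML file path.
#' @return A named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A named list with the same structure (built in code).
#' @export
validate_run_config <- function(config) {
  paths <- config$paths
  for (p in c("transcripts", "segments", "lexicon")) {
    if (is.null(paths[[p]])) {
      stop("run config must name paths$", p, call. = FALSE)
    }
    if (!file.exists(paths[[p]])) {
      stop("configured path does not exist: ", paths[[p]], call. = FALSE)
    }
  }
  config$seed <- config$seed %||% 1L
  config$preprocess <- config$preprocess %||% list()
  config$embed <- config$embed %||% list()
  config$stats <- config$stats %||% list()
  structure(config, class = c("run_config", "list"))
}

# transcripts/segments directories hold <GROUP>_s<NN>.txt files
load_study <- function(config) {
  parse_name <- function(f) {
    m <- stringr::str_match(basename(f), "^([A-Za-z0-9]+)_s(\\d+)\\.txt$")
    if (anyNA(m)) stop("unrecognized corpus file name: ", basename(f),
                       " (expected <GROUP>_s<NN>.txt)", call. = FALSE)
    list(group = m[2], session = as.integer(m[3]))
  }
  tfiles <- list.files(config$paths$transcripts, pattern = "\\.txt$",
                       full.names = TRUE)
  sfiles <- list.files(config$paths$segments, pattern = "\\.txt$",
                       full.names = TRUE)
  if (!length(tfiles)) stop("no transcript files found", call. = FALSE)
  transcripts <- purrr::map_dfr(tfiles, function(f) {
    id <- parse_name(f)
    read_transcript(f, id$group, id$session)
  })
  segments <- purrr::map_dfr(sfiles, function(f) {
    id <- parse_name(f)
    read_segment(f, id$group, id$session)
  })
  lexicon <- read_lexicon(config$paths$lexicon)
  feedback <- NULL
  if (!is.null(config$paths$feedback) &&
      file.exists(config$paths$feedback)) {
    feedback <- read_feedback(config$paths$feedback)
  }
  list(transcripts = transcripts, segments = segments, lexicon = lexicon,
       feedback = feedback)
}

study_embed_config <- function(config, window, n_docs) {
  args <- config$embed
  if (is.null(args$window) || identical(args$window, "auto")) {
    args$window <- max(1L, as.integer(round(window)))
  }
  args$seed <- args$seed %||% config$seed
  do.call(embed_config, args)
}

#' Run the full analysis pipeline in memory
#'
#' The computational core behind the `run_*` writers: cleans the corpus,
#' scores VAD, builds tier reports, trains one paragraph-vector model per
#' group (window = rounded group mean sentence length unless configured),
#' computes similarity matrices and the per-session text-discussion
#' similarities, and fits the correlation and group-comparison
#' statistics. Nothing is written to disk.
#'
#' @param config A `run_config` (see [read_run_config()]); alternatively
#'   pass `study` directly.
#' @param study Optional pre-loaded list with `transcripts`, `segments`,
#'   `lexicon`, `feedback` (as produced by [make_corpus()] or
#'   [load_study]).
#' @return Named list of result tables: `docs`, `sentence_stats`,
#'   `profiles`, `term_summary`, `tiers`, `models`, `similarity`,
#'   `text_similarity`, `records`, `correlations`, `vad_tests`,
#'   `feedback_tests` (NULL without feedback data).
#' @export
analyse_study <- function(config, study = NULL) {
  study <- study %||% load_study(config)
  pp <- config$preprocess %||% list()
  docs <- clean_corpus(study$transcripts, study$segments,
                       keep_stage_directions =
                         isTRUE(pp$keep_stage_directions))
  sstats <- sentence_stats(study$transcripts)
  profiles <- score_docs(docs, study$lexicon,
                         sd_method = pp$sd_method %||% "sample")
  summaries <- purrr::map(
    stats::setNames(unique(docs$group_id), unique(docs$group_id)),
    function(g) {
      vad_group_summary(docs[docs$group_id == g, ], study$lexicon,
                        sd_method = pp$sd_method %||% "sample")
    })
  term_summary <- purrr::map_dfr(summaries, "term")
  tiers <- purrr::map_dfr(unique(docs$group_id), function(g) {
    purrr::map_dfr(c("valence", "arousal", "dominance"), function(d) {
      dplyr::mutate(
        decile_tiers(docs[docs$group_id == g &
                            docs$kind == "discussion", ],
                     study$lexicon, dimension = d),
        group_id = g, .before = 1)
    })
  })
  groups <- unique(docs$group_id)
  models <- purrr::map(stats::setNames(groups, groups), function(g) {
    w <- sstats$mean_sentence_length[sstats$group_id == g]
    train_pvdbow(docs[docs$group_id == g, ],
                 study_embed_config(config, w,
                                    sum(docs$group_id == g)))
  })
  similarity <- purrr::map_dfr(groups, function(g) {
    dplyr::mutate(similarity_matrix(models[[g]], rescale01 = TRUE),
                  group_id = g, .before = 1)
  })
  text_sim <- purrr::map(groups, function(g) {
    text_discussion_similarity(models[[g]], docs[docs$group_id == g, ])
  })
  sessions_sim <- purrr::map_dfr(text_sim, "sessions")
  records <- dplyr::inner_join(
    sessions_sim,
    profiles[profiles$kind == "discussion", ],
    by = c("group_id", "session")
  )
  correlations <- similarity_vad_correlation(
    records, measure = config$stats$measure %||% "mean")
  vad_tests <- if (length(groups) == 2) {
    vad_group_test(profiles[profiles$kind == "discussion", ],
                   order = groups,
                   equal_var = !isFALSE(config$stats$equal_var))
  }
  feedback_tests <- if (!is.null(study$feedback)) {
    feedback_comparison(study$feedback, order = groups,
                        adjust = config$stats$adjust %||% "none",
                        equal_var = !isFALSE(config$stats$equal_var))
  }
  list(docs = docs, sentence_stats = sstats, profiles = profiles,
       term_summary = term_summary, tiers = tiers, models = models,
       similarity = similarity,
       text_similarity = list(sessions = sessions_sim,
                              groups = purrr::map_dfr(text_sim, "groups")),
       records = records, correlations = correlations,
       vad_tests = vad_tests, feedback_tests = feedback_tests)
}

write_results <- function(results, config, which, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writers <- list(
    vad = function() {
      write_table(results$profiles, file.path(out_dir, "vad_profiles.csv"))
      write_table(results$term_summary,
                  file.path(out_dir, "vad_term_summary.csv"))
      write_table(results$sentence_stats,
                  file.path(out_dir, "sentence_stats.csv"))
    },
    tiers = function() {
      write_table(results$tiers, file.path(out_dir, "vad_tiers.csv"))
    },
    embed = function() {
      write_table(results$similarity,
                  file.path(out_dir, "similarity_matrix.csv"))
      write_table(results$text_similarity$sessions,
                  file.path(out_dir, "text_similarity_sessions.csv"))
      write_table(results$text_similarity$groups,
                  file.path(out_dir, "text_similarity_groups.csv"))
      purrr::iwalk(results$models, function(m, g) {
        write_pvdbow(m, file.path(out_dir, paste0("model_", g)))
      })
    },
    correlate = function() {
      write_table(results$correlations$pooled,
                  file.path(out_dir, "similarity_vad_correlations.csv"))
      write_table(results$correlations$by_group,
                  file.path(out_dir,
                            "similarity_vad_correlations_by_group.csv"))
      if (!is.null(results$vad_tests)) {
        write_table(results$vad_tests,
                    file.path(out_dir, "vad_group_tests.csv"))
      }
      if (!is.null(results$feedback_tests)) {
        write_table(results$feedback_tests,
                    file.path(out_dir, "feedback_tests.csv"))
      }
    }
  )
  for (w in which) writers[[w]]()
  meta_files <- c(lexicon = config$paths$lexicon,
                  stopwords = system.file("extdata", "stopwords_en.txt",
                                          package = "groupreadr"),
                  lemmas = system.file("extdata", "lemmas_en.tsv",
                                       package = "groupreadr"))
  write_run_metadata(
    list(seed = config$seed, preprocess = config$preprocess,
         embed = purrr::map(results$models,
                            function(m) unclass(m$config)),
         stats = config$stats, commands = which),
    file.path(out_dir, "run_metadata.json"), files = meta_files)
  invisible(out_dir)
}

#' Pipeline commands
#'
#' Each command recomputes its stage from the configured inputs and writes
#' CSV tables plus run metadata (seeds, hyperparameters, resource
#' checksums) into the configured output directory. All computation
#' happens before any file is written, so a failure leaves no partial
#' outputs. `run_report()` is the union of the other commands' outputs.
#'
#' @param config A `run_config` from [read_run_config()] /
#'   [validate_run_config()].
#' @param out Output directory; defaults to `config$paths$out`.
#' @return The output directory, invisibly.
#' @export
run_vad <- function(config, out = NULL) {
  out <- out %||% config$paths$out
  write_results(analyse_study(config), config, "vad", out)
}

#' @rdname run_vad
#' @export
run_tiers <- function(config, out = NULL) {
  out <- out %||% config$paths$out
  write_results(analyse_study(config), config, "tiers", out)
}

#' @rdname run_vad
#' @export
run_embed <- function(config, out = NULL) {
  out <- out %||% config$paths$out
  write_results(analyse_study(config), config, "embed", out)
}

#' @rdname run_vad
#' @export
run_correlate <- function(config, out = NULL) {
  out <- out %||% config$paths$out
  write_results(analyse_study(config), config, "correlate", out)
}

#' @rdname run_vad
#' @export
run_report <- function(config, out = NULL) {
  out <- out %||% config$paths$out
  write_results(analyse_study(config), config,
                c("vad", "tiers", "embed", "correlate"), out)
}

#' Generate a synthetic fixture study on disk
#'
#' @param synth A [synth_config()] (or a YAML path holding its fields).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
run_simulate <- function(synth = synth_config(), dir) {
  if (is.character(synth)) {
    synth <- do.call(synth_config, yaml::read_yaml(synth))
  }
  make_corpus(synth, dir = dir)
  invisible(dir)
}
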