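#' Paragraph-vector training configuration
#'
#' Hyperparameters of the PV-DBOW model. The two parameters the analysis
#' is most sensitive to are the context `window` — set per group to the
#' rounded mean sentence length of its discussions, since the window is a
#' discourse specifier — and `epochs`, which defaults to 30000 full passes,
#' the point at which results stabilize on corpora of this size. Desk-scale
#' runs use far fewer epochs.
#'
#' @param dim Vector dimensionality (>= 2).
#' @param window Context span in tokens from which each position's target
#'   word is sampled (>= 1).
#' @param epochs Training passes over the corpus (>= 1).
#' @param negatives Negative samples per positive (>= 1), drawn from the
#'   unigram distribution raised to 0.75.
#' @param lr_start,lr_end Linear learning-rate schedule endpoints,
#'   `lr_start >= lr_end > 0`.
#' @param seed Master RNG seed; every sampling stream (initialization,
#'   window targets, negatives) derives from it, making training
#'   bit-reproducible.
#' @param min_count Vocabulary frequency floor (1 keeps everything; the
#'   corpora are tiny).
#' @return An `embed_config` list.
#' @export
embed_config <- function(dim = 100, window = 12, epochs = 30000,
                         negatives = 5, lr_start = 0.025, lr_end = 1e-4,
                         seed = 1L, min_count = 1) {
  stopifnot(dim >= 2, window >= 1, epochs >= 1, negatives >= 1,
            lr_start >= lr_end, lr_end > 0, min_count >= 1)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 epochs = as.integer(epochs),
                 negatives = as.integer(negatives),
                 lr_start = lr_start, lr_end = lr_end,
                 seed = as.integer(seed), min_count = as.integer(min_count)),
            class = "embed_config")
}

#' Train a PV-DBOW paragraph-vector model
#'
#' Distributed bag-of-words paragraph vectors: each document carries a
#' trainable vector, and for every token position a target word is sampled
#' from the surrounding window and predicted from the document vector
#' alone, with negative sampling
#' (`log sigma(u_w . d) + sum_k log sigma(-u_k . d)`), SGD and a linear
#' learning-rate decay. Updates are single-threaded in fixed order with a
#' dedicated RNG, so a given (corpus, config) pair always yields identical
#' vectors.
#'
#' @param docs Document tibble from [clean_corpus()] (or any tibble with
#'   `doc_id` and a `lemmas` list column).
#' @param config An [embed_config()].
#' @return A `pvdbow_model`: list with `doc_vectors` (docs x dim, rownames
#'   = doc_id), `word_vectors` (vocab x dim), `vocab` tibble (lemma,
#'   count), `config`, `epoch_loss`, `final_loss`.
#' @export
train_pvdbow <- function(docs, config = embed_config()) {
  stopifnot(inherits(config, "embed_config"))
  lemmas <- docs$lemmas
  counts <- table(unlist(lemmas))
  counts <- counts[counts >= config$min_count]
  if (length(counts) < 2L) {
    stop("post-filter vocabulary has fewer than 2 types; cannot train",
         call. = FALSE)
  }
  # deterministic vocabulary order: frequency desc, then lemma
  vocab <- tibble::tibble(lemma = names(counts),
                          count = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$lemma)
  idx <- stats::setNames(seq_len(nrow(vocab)) - 1L, vocab$lemma)
  enc <- lapply(lemmas, function(x) unname(idx[x[x %in% vocab$lemma]]))
  empty <- lengths(enc) == 0L
  if (any(empty)) {
    stop("document(s) empty after min_count filtering: ",
         paste(docs$doc_id[empty], collapse = ", "), call. = FALSE)
  }
  fit <- cpp_pvdbow_train(enc, nrow(vocab), as.numeric(vocab$count),
                          config$dim, config$window, config$epochs,
                          config$negatives, config$lr_start, config$lr_end,
                          as.double(config$seed))
  rownames(fit$doc_vectors) <- docs$doc_id
  rownames(fit$word_vectors) <- vocab$lemma
  structure(list(doc_vectors = fit$doc_vectors,
                 word_vectors = fit$word_vectors,
                 vocab = vocab, config = config,
                 epoch_loss = as.numeric(fit$epoch_loss),
                 final_loss = fit$epoch_loss[config$epochs]),
            class = "pvdbow_model")
}

#' @export
print.pvdbow_model <- function(x, ...) {
  cat("PV-DBOW model:", nrow(x$doc_vectors), "docs,",
      nrow(x$vocab), "vocabulary types, dim", x$config$dim, "\n")
  cat("  epochs:", x$config$epochs, " window:", x$config$window,
      " seed:", x$config$seed, "\n")
  cat("  final mean objective:", format(x$final_loss, digits = 5), "\n")
  invisible(x)
}

cosine <- function(a, b) {
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

#' Cosine similarity matrix between document vectors
#'
#' @param model A `pvdbow_model`.
#' @param rows,cols Character vectors of `doc_id`s (default: all).
#' @param rescale01 If `TRUE`, map cosine `s` to `(s + 1) / 2` so the
#'   values sit on the `[0, 1]` display scale used by the similarity
#'   heatmaps (raw cosine stays the analysis default).
#' @return A tidy tibble with columns `row_id`, `col_id`, `similarity`,
#'   of class `sim_tbl`; reshape with [sim_matrix()].
#' @export
similarity_matrix <- function(model, rows = NULL, cols = NULL,
                              rescale01 = FALSE) {
  ids <- rownames(model$doc_vectors)
  rows <- rows %||% ids
  cols <- cols %||% ids
  unknown <- setdiff(c(rows, cols), ids)
  if (length(unknown)) {
    stop("unknown doc_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  V <- model$doc_vectors / sqrt(rowSums(model$doc_vectors^2))
  S <- V[rows, , drop = FALSE] %*% t(V[cols, , drop = FALSE])
  if (rescale01) S <- (S + 1) / 2
  out <- tibble::tibble(
    row_id = rep(rows, times = length(cols)),
    col_id = rep(cols, each = length(rows)),
    similarity = as.vector(S)
  )
  class(out) <- c("sim_tbl", class(out))
  out
}

#' Widen a tidy similarity table into a matrix
#'
#' @param sim A `sim_tbl` from [similarity_matrix()].
#' @return A numeric matrix with row/col names.
#' @export
sim_matrix <- function(sim) {
  rows <- unique(sim$row_id)
  cols <- unique(sim$col_id)
  m <- matrix(sim$similarity, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  m
}

#' Per-session text-discussion similarity
#'
#' Pairs each session's discussion with the literary segment read in it
#' and reports their cosine similarity, plus the group-level mean — the
#' quantity behind "one group was more on topic than the other".
#'
#' @param model A `pvdbow_model` trained on a [clean_corpus()] table
#'   containing both kinds of document.
#' @param docs The document tibble the model was trained on.
#' @return A list of tibbles: `sessions` (`group_id`, `session`,
#'   `similarity`) and `groups` (`group_id`, `mean_similarity`,
#'   `n_sessions`).
#' @export
text_discussion_similarity <- function(model, docs) {
  pairs <- docs |>
    dplyr::distinct(.data$group_id, .data$session, .data$kind,
                    .data$doc_id) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "doc_id")
  if (!all(c("discussion", "text") %in% names(pairs)) ||
      anyNA(pairs$discussion) || anyNA(pairs$text)) {
    bad <- if (all(c("discussion", "text") %in% names(pairs))) {
      pairs[is.na(pairs$discussion) | is.na(pairs$text), ]
    } else pairs
    stop("unpaired session(s): each session needs exactly one discussion ",
         "and one text document (",
         paste(paste0(bad$group_id, "/", bad$session), collapse = ", "),
         ")", call. = FALSE)
  }
  sims <- purrr::map2_dbl(pairs$discussion, pairs$text, function(d, t) {
    cosine(model$doc_vectors[d, ], model$doc_vectors[t, ])
  })
  sessions <- tibble::tibble(group_id = pairs$group_id,
                             session = pairs$session, similarity = sims)
  groups <- sessions |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(mean_similarity = mean(.data$similarity),
                     n_sessions = dplyr::n(), .groups = "drop")
  list(sessions = sessions, groups = groups)
}

#' PV-DBOW objective for one training triple
#'
#' The negative-sampling loss
#' `-(log sigma(u_w . d) + sum_k log sigma(-u_k . d))` for one document
#' vector, target word output vector and matrix of negative-word output
#' vectors — the quantity each SGD step descends. Exposed together with
#' [pvdbow_point_grad()] so the analytic gradient can be verified against
#' finite differences.
#'
#' @param doc Numeric document vector.
#' @param word Numeric target-word output vector.
#' @param neg Numeric matrix of negative-word output vectors (one row per
#'   negative).
#' @return Scalar loss.
#' @export
pvdbow_point_loss <- function(doc, word, neg) {
  cpp_pvdbow_point_loss(doc, word, as.matrix(neg))
}

#' Analytic gradient of the PV-DBOW point objective
#'
#' @inheritParams pvdbow_point_loss
#' @return List with elements `doc`, `word`, `neg`: gradients of
#'   [pvdbow_point_loss()] with respect to each input.
#' @export
pvdbow_point_grad <- function(doc, word, neg) {
  cpp_pvdbow_point_grad(doc, word, as.matrix(neg))
}

#' Persist / restore a PV-DBOW model as portable text artefacts
#'
#' Writes the vocabulary as TSV, both vector blocks as CSV and the config
#' as JSON under `dir`; `read_pvdbow()` restores an identical model.
#'
#' @param model A `pvdbow_model`.
#' @param dir Directory to write into (created if needed).
#' @return `dir` (write) or a `pvdbow_model` (read), invisibly/visibly.
#' @export
write_pvdbow <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(model$vocab, file.path(dir, "vocab.tsv"),
                   progress = FALSE)
  utils::write.csv(model$doc_vectors, file.path(dir, "doc_vectors.csv"))
  utils::write.csv(model$word_vectors, file.path(dir, "word_vectors.csv"))
  jsonlite::write_json(unclass(model$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  readr::write_lines(format(model$epoch_loss, digits = 17),
                     file.path(dir, "epoch_loss.txt"))
  invisible(dir)
}

#' @rdname write_pvdbow
#' @export
read_pvdbow <- function(dir) {
  vocab <- readr::read_tsv(file.path(dir, "vocab.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  dv <- as.matrix(utils::read.csv(file.path(dir, "doc_vectors.csv"),
                                  row.names = 1, check.names = FALSE))
  wv <- as.matrix(utils::read.csv(file.path(dir, "word_vectors.csv"),
                                  row.names = 1, check.names = FALSE))
  colnames(dv) <- NULL
  colnames(wv) <- NULL
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  loss <- as.numeric(readr::read_lines(file.path(dir, "epoch_loss.txt")))
  structure(list(doc_vectors = dv, word_vectors = wv, vocab = vocab,
                 config = do.call(embed_config, cfg), epoch_loss = loss,
                 final_loss = loss[length(loss)]),
            class = "pvdbow_model")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PV-DBOW model into a long tibble of document coordinates
#'
#' @param x A `pvdbow_model`.
#' @param ... Unused.
#' @return Tibble with columns `doc_id`, `dimension`, `value`.
#' @method tidy pvdbow_model
#' @export
tidy.pvdbow_model <- function(x, ...) {
  tibble::tibble(
    doc_id = rep(rownames(x$doc_vectors), times = ncol(x$doc_vectors)),
    dimension = rep(seq_len(ncol(x$doc_vectors)),
                    each = nrow(x$doc_vectors)),
    value = as.vector(x$doc_vectors)
  )
}

#' One-row model summary
#'
#' @param x A `pvdbow_model`.
#' @param ... Unused.
#' @return One-row tibble: `n_docs`, `vocab_size`, `dim`, `window`,
#'   `epochs`, `negatives`, `seed`, `final_loss`.
#' @method glance pvdbow_model
#' @export
glance.pvdbow_model <- function(x, ...) {
  tibble::tibble(n_docs = nrow(x$doc_vectors), vocab_size = nrow(x$vocab),
                 dim = x$config$dim, window = x$config$window,
                 epochs = x$config$epochs, negatives = x$config$negatives,
                 seed = x$config$seed, final_loss = x$final_loss)
}
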