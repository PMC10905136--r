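#' Read a speaker-coded discussion transcript
#'
#' Transcripts are UTF-8 plain text in which each utterance starts on a line
#' prefixed with an upper-case speaker pseudonym and a colon (the study
#' convention pseudonymizes speakers with colour codes, e.g. `GOLD:`).
#' Lines without a speaker prefix are continuations of the preceding
#' utterance and are joined with single spaces. Bracketed stage directions
#' such as `[laughter]` are preserved verbatim here; [tokenize()] strips
#' them later so the raw data are never destroyed.
#'
#' @param path Path to a UTF-8 transcript file.
#' @param group_id Group label, e.g. `"MT"` or `"HT"`.
#' @param session 1-based session number.
#'
#' @return A tibble with one row per utterance and columns `group_id`,
#'   `session`, `index` (0-based utterance position), `speaker`, `text`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("GOLD: I might agree,", "YELLOW: Yeah, fair point."), f)
#' read_transcript(f, "MT", 1)
read_transcript <- function(path, group_id, session) {
  if (!file.exists(path)) {
    stop("transcript file not found: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  tag <- "^([A-Z][A-Z0-9_-]*):\\s*"
  is_start <- grepl(tag, lines)
  if (length(lines) == 0L || !any(is_start)) {
    offending <- if (length(lines)) lines[[1]] else "<empty file>"
    stop("no speaker-prefixed line found in ", path,
         "; first line: ", offending, call. = FALSE)
  }
  if (!is_start[[1]]) {
    stop("transcript must begin with a speaker-prefixed line; first line: ",
         lines[[1]], call. = FALSE)
  }
  utt <- cumsum(is_start)
  speakers <- sub(paste0(tag, ".*$"), "\\1", lines[is_start])
  bodies <- sub(tag, "", lines)
  texts <- vapply(split(bodies, utt), paste, character(1), collapse = " ")
  tibble::tibble(
    group_id = group_id,
    session = as.integer(session),
    index = seq_along(speakers) - 1L,
    speaker = speakers,
    text = unname(texts)
  )
}

#' Read a literary segment
#'
#' One plain-text file per session holding the portion of the literary text
#' read and discussed in that session. An optional first line of the form
#' `# title` is taken as the segment title.
#'
#' @inheritParams read_transcript
#' @return A one-row tibble with columns `group_id`, `session`, `title`,
#'   `text`.
#' @export
read_segment <- function(path, group_id, session) {
  if (!file.exists(path)) {
    stop("segment file not found: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path)
  title <- NA_character_
  if (length(lines) && grepl("^#\\s*", lines[[1]])) {
    title <- sub("^#\\s*", "", lines[[1]])
    lines <- lines[-1]
  }
  text <- paste(lines[!grepl("^\\s*$", lines)], collapse = " ")
  if (!nzchar(text)) stop("segment file is empty: ", path, call. = FALSE)
  tibble::tibble(
    group_id = group_id, session = as.integer(session),
    title = title, text = text
  )
}

#' Default column mapping for Warriner-style norm files
#'
#' The published affective-norms file uses columns `Word`, `V.Mean.Sum`,
#' `A.Mean.Sum`, `D.Mean.Sum` for the lemma and the mean valence, arousal
#' and dominance ratings on a 1-9 scale.
#'
#' @return Named list mapping roles (`lemma`, `valence`, `arousal`,
#'   `dominance`) to CSV column names.
#' @export
warriner_dialect <- function() {
  list(lemma = "Word", valence = "V.Mean.Sum",
       arousal = "A.Mean.Sum", dominance = "D.Mean.Sum")
}

#' Read a VAD word-norm lexicon
#'
#' Reads a CSV of human word-norm ratings: one lemma per row with mean
#' valence, arousal and dominance on the published 1-9 rating scale.
#' Lemmas are lowercased; duplicate lemmas keep the first occurrence (a
#' warning reports how many were dropped). Values outside the source scale
#' are a validation error.
#'
#' @param path CSV path with a header row.
#' @param dialect Named list mapping the roles `lemma`, `valence`,
#'   `arousal`, `dominance` to column names. Defaults to
#'   [warriner_dialect()]; if those columns are absent, plain columns named
#'   `lemma`, `valence`, `arousal`, `dominance` are used instead.
#' @param scale Numeric length-2 `c(min, max)` of the source rating scale.
#'
#' @return A tibble with columns `lemma`, `valence`, `arousal`, `dominance`
#'   (raw scale values) and attribute `scale`.
#' @export
read_lexicon <- function(path, dialect = warriner_dialect(),
                         scale = c(1, 9)) {
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  roles <- c("lemma", "valence", "arousal", "dominance")
  cols <- unlist(dialect[roles])
  if (!all(cols %in% names(raw)) && all(roles %in% names(raw))) {
    cols <- stats::setNames(roles, roles)
  }
  missing <- setdiff(cols, names(raw))
  if (length(missing)) {
    stop("lexicon is missing mapped column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lex <- tibble::tibble(
    lemma = tolower(as.character(raw[[cols[["lemma"]]]])),
    valence = as.numeric(raw[[cols[["valence"]]]]),
    arousal = as.numeric(raw[[cols[["arousal"]]]]),
    dominance = as.numeric(raw[[cols[["dominance"]]]])
  )
  vals <- as.matrix(lex[, c("valence", "arousal", "dominance")])
  bad <- which(rowSums(vals < scale[1] | vals > scale[2] | is.na(vals)) > 0)
  if (length(bad)) {
    stop("lexicon values outside [", scale[1], ", ", scale[2], "] in row(s): ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(lex$lemma)
  if (any(dup)) {
    warning(sum(dup), " duplicate lemma(s) dropped (first occurrence kept)",
            call. = FALSE)
    lex <- lex[!dup, ]
  }
  if (nrow(lex) == 0L) stop("lexicon is empty", call. = FALSE)
  attr(lex, "scale") <- scale
  lex
}

#' Read a per-participant feedback score table
#'
#' @param path CSV with columns `participant`, `group_id`, `item`, `score`
#'   (scores on the questionnaire's 0-5 agreement scale).
#' @return A tibble with those columns, `score` numeric.
#' @export
read_feedback <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant", "group_id", "item", "score")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("feedback table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(tab[need], score = as.numeric(.data$score))
}

#' Write an output table as CSV
#'
#' @param rows A data frame.
#' @param path Destination path; parent directory must exist and be
#'   writable.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' Write run metadata for reproducibility
#'
#' Records everything needed to reproduce a run bit-for-bit: the seed, all
#' hyperparameters, the stopword inventory and MD5 checksums of external
#' resource files (lexicon, stopwords, lemma dictionary).
#'
#' @param config Named list of run settings (seeds, hyperparameters, paths).
#' @param path Destination JSON path.
#' @param files Optional named character vector of resource file paths to
#'   checksum.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path, files = NULL) {
  meta <- list(
    package = "groupreadr",
    version = as.character(utils::packageVersion("groupreadr")),
    r_version = as.character(getRversion()),
    config = config
  )
  if (!is.null(files)) {
    files <- files[file.exists(files)]
    sums <- unname(tools::md5sum(files))
    meta$checksums <- as.list(stats::setNames(sums, names(files)))
  }
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Convert a deposited spreadsheet to the CSV formats the package reads
#'
#' The study's archived data ship as spreadsheets. The core readers parse
#' only plain text and CSV, so spreadsheets are converted first. Conversion
#' uses the Python `openpyxl` library through a system call; each sheet
#' becomes `<out_dir>/<sheet>.csv`.
#'
#' @param path Path to an `.xlsx` file.
#' @param out_dir Output directory for the per-sheet CSV files.
#' @param python Python interpreter to use.
#' @return Character vector of written CSV paths.
#' @export
convert_xlsx <- function(path, out_dir, python = "python") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  script <- system.file("python", "xlsx2csv.py", package = "groupreadr")
  status <- system2(python, c(script, shQuote(path), shQuote(out_dir)))
  if (status != 0) stop("spreadsheet conversion failed", call. = FALSE)
  list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
}
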