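#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation via the t transform (delegated to
#' [stats::cor.test()]), returned in tidy form.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return One-row tibble: `r`, `n`, `t`, `df`, `p`.
#' @export
#' @examples
#' pearson_cor(1:4, c(1, 3, 2, 4))
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance in x or y; correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), n = length(x),
                 t = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value)
}

#' Correlate text-discussion similarity with session emotion
#'
#' For each VAD dimension, the Pearson correlation between the per-session
#' text-discussion cosine similarity and a session emotion variable: the
#' session mean by default (the reading "the greater the similarity, the
#' lower the arousal"), or the within-session word-level SD as an explicit
#' volatility measure. Sessions are pooled across groups by default (one
#' printed coefficient per dimension implies pooling); per-group
#' coefficients are also returned.
#'
#' @param records Tibble with one row per (group, session): columns
#'   `group_id`, `session`, `similarity`, `valence`, `arousal`,
#'   `dominance` and (if `measure = "sd"`) `valence_sd`, `arousal_sd`,
#'   `dominance_sd` — the join of [text_discussion_similarity()]`$sessions`
#'   with [score_docs()] discussion rows.
#' @param measure `"mean"` (default) or `"sd"`.
#' @return A list of tibbles: `pooled` (one row per dimension: `dimension`,
#'   `r`, `n`, `t`, `df`, `p`, `ns` flag at alpha = .05) and `by_group`.
#' @export
similarity_vad_correlation <- function(records, measure = c("mean", "sd")) {
  measure <- match.arg(measure)
  dims <- c("valence", "arousal", "dominance")
  cols <- if (measure == "mean") dims else paste0(dims, "_sd")
  one <- function(df) {
    purrr::map2_dfr(dims, cols, function(d, cl) {
      dplyr::mutate(pearson_cor(df$similarity, df[[cl]]), dimension = d,
                    .before = 1)
    }) |>
      dplyr::mutate(ns = .data$p >= 0.05)
  }
  pooled <- one(records)
  by_group <- records |>
    dplyr::group_split(.data$group_id) |>
    purrr::map_dfr(function(grp) {
      gid <- grp$group_id[[1]]
      dplyr::mutate(one(grp), group_id = gid, .before = 1)
    })
  list(pooled = pooled, by_group = by_group)
}

#' Independent-samples t-test in tidy form
#'
#' Student's equal-variance test by default (the conventional reading for
#' small samples); Welch's unequal-variance test via `equal_var = FALSE`.
#' The sign convention is `mean(a) - mean(b)` with `a` the first group.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param equal_var Pool variances (default `TRUE`).
#' @param label Optional variable label carried into the result.
#' @return One-row tibble: `variable`, `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b, equal_var = TRUE, label = NA_character_) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  if (var(a) == 0 && var(b) == 0) {
    # degenerate constant data: define t = 0 when means agree (p = 1),
    # +/-Inf otherwise; stats::t.test refuses this case outright
    d <- mean(a) - mean(b)
    df <- if (equal_var) length(a) + length(b) - 2 else NA_real_
    return(tibble::tibble(variable = label,
                          t = if (d == 0) 0 else sign(d) * Inf,
                          df = df, p = if (d == 0) 1 else 0,
                          mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = equal_var, alternative = "two.sided")
  tibble::tibble(variable = label, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 mean_a = mean(a), mean_b = mean(b))
}

#' Between-group comparison of per-session VAD means
#'
#' One independent-samples t-test per VAD dimension comparing the two
#' groups' per-session discussion means (sessions are the units, as in the
#' session-level emotional-profile comparison).
#'
#' @param profiles Discussion profile tibble from [score_docs()].
#' @param order Character vector giving the group order; the first group
#'   is `a` in the sign convention.
#' @inheritParams two_sample_t
#' @return Tibble with one row per dimension.
#' @export
vad_group_test <- function(profiles, order = NULL, equal_var = TRUE) {
  groups <- order %||% sort(unique(profiles$group_id))
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  purrr::map_dfr(c("valence", "arousal", "dominance"), function(d) {
    two_sample_t(profiles[[d]][profiles$group_id == groups[1]],
                 profiles[[d]][profiles$group_id == groups[2]],
                 equal_var = equal_var, label = d)
  })
}

#' Per-item feedback comparison between groups
#'
#' One independent-samples t-test per questionnaire item (scores on the
#' 0-5 agreement scale), flagging items with p < .05. No multiple-testing
#' correction is applied by default, matching the raw per-item p-values
#' convention; Benjamini-Hochberg adjusted p-values are available because
#' testing 32 items at alpha = .05 uncorrected is a known weakness.
#'
#' @param feedback Tibble with columns `participant`, `group_id`, `item`,
#'   `score` (see [read_feedback()]).
#' @param order Group order; first group is `a` in the sign convention.
#' @param adjust `"none"` (default) or `"BH"`.
#' @inheritParams two_sample_t
#' @return Tibble with one row per item: `item`, `t`, `df`, `p`,
#'   (`p_adj`), `mean_a`, `mean_b`, `significant`.
#' @export
feedback_comparison <- function(feedback, order = NULL,
                                adjust = c("none", "BH"),
                                equal_var = TRUE) {
  adjust <- match.arg(adjust)
  need <- c("participant", "group_id", "item", "score")
  if (!all(need %in% names(feedback))) {
    stop("feedback table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  groups <- order %||% sort(unique(feedback$group_id))
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  res <- feedback |>
    dplyr::group_split(.data$item) |>
    purrr::map_dfr(function(grp) {
      out <- two_sample_t(grp$score[grp$group_id == groups[1]],
                          grp$score[grp$group_id == groups[2]],
                          equal_var = equal_var)
      it <- grp$item[[1]]
      dplyr::mutate(out, item = it, .before = 1, variable = NULL)
    })
  p_used <- if (adjust == "BH") p.adjust(res$p, method = "BH") else res$p
  res$significant <- p_used < 0.05
  if (adjust == "BH") res$p_adj <- p_used
  res
}
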