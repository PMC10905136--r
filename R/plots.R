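#' Session-by-session VAD profile plot
#'
#' Line plot of per-session mean valence, arousal and dominance by group,
#' on the common `[0, 1]` scale. A convenience rendering of the profile
#' table, which remains the source of truth.
#'
#' @param profiles Profile tibble from [score_docs()].
#' @param kind Which documents to plot.
#' @return A ggplot object.
#' @export
plot_vad_sessions <- function(profiles, kind = "discussion") {
  df <- profiles[profiles$kind == kind, ] |>
    tidyr::pivot_longer(c("valence", "arousal", "dominance"),
                        names_to = "dimension", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$session, .data$value,
                                   colour = .data$dimension)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~group_id) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Session", y = "Mean value (0-1)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Similarity heatmap
#'
#' Heatmap of a document-document cosine similarity table (lighter = more
#' similar), as used to compare transcripts with the texts read.
#'
#' @param sim A `sim_tbl` from [similarity_matrix()].
#' @return A ggplot object.
#' @export
plot_similarity_heatmap <- function(sim) {
  ggplot2::ggplot(sim, ggplot2::aes(.data$col_id, .data$row_id,
                                    fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(0, min(sim$similarity)),
                                             1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @method autoplot sim_tbl
#' @export
autoplot.sim_tbl <- function(object, ...) plot_similarity_heatmap(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tier word plot
#'
#' Frequency-scaled text plot of a decile tier report: the package's
#' text-based stand-in for the word-cloud rendering of tier membership.
#'
#' @param tiers Tier report from [decile_tiers()].
#' @param max_words Most frequent words shown per tier.
#' @return A ggplot object.
#' @export
plot_tier_words <- function(tiers, max_words = 25) {
  df <- tiers |>
    dplyr::group_by(.data$tier) |>
    dplyr::slice_max(.data$frequency, n = max_words, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$frequency,
                                   label = .data$lemma,
                                   size = .data$frequency)) +
    ggplot2::geom_text(check_overlap = TRUE) +
    ggplot2::facet_wrap(~tier, scales = "free_x") +
    ggplot2::scale_size_continuous(range = c(2.5, 6), guide = "none") +
    ggplot2::labs(x = paste0(unique(tiers$dimension), " (0-1)"),
                  y = "Corpus frequency") +
    ggplot2::theme_minimal()
}
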