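#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a card's reaction-similarity structure
#'
#' Gene- and EC-perspective cards show the all-pairs overlap matrix as a
#' tile plot colored by agreement band; reaction-perspective cards show the
#' per-row overlap against the focus reaction as a bar chart.
#'
#' @param object A `c2_card`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.c2_card <- function(object, ...) {
  band_fill <- ggplot2::scale_fill_manual(
    values = c(exact = "#1a9850", high = "#fee08b", partial = "#fdae61",
               none = "#d73027"),
    drop = FALSE, name = "agreement")
  if (object$focus$kind == "reaction") {
    d <- object$similarity %>%
      mutate(key = rec_key(.data$source_db, .data$local_id),
             band = overlap_band(.data$percent_display))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$percent_display,
                                    y = stats::reorder(.data$key,
                                                       .data$percent_display),
                                    fill = .data$band)) +
      ggplot2::geom_col() +
      band_fill +
      ggplot2::labs(x = "overlap vs focus (%)", y = NULL,
                    title = paste0("Reaction card: ", object$focus$key)) +
      ggplot2::xlim(0, 100) +
      ggplot2::theme_minimal()
  } else {
    d <- object$similarity
    if (nrow(d) == 0L) {
      return(ggplot2::ggplot() + ggplot2::theme_void() +
               ggplot2::labs(title = "single-reaction card"))
    }
    d <- bind_rows(
      d %>% transmute(a = rec_key(.data$db1, .data$reaction1),
                      b = rec_key(.data$db2, .data$reaction2),
                      p = .data$percent_display),
      d %>% transmute(a = rec_key(.data$db2, .data$reaction2),
                      b = rec_key(.data$db1, .data$reaction1),
                      p = .data$percent_display)) %>%
      distinct()
    keys <- sort(unique(c(d$a, d$b)))
    d <- bind_rows(d, tibble(a = keys, b = keys, p = 100L)) %>%
      mutate(band = overlap_band(.data$p))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b,
                                    fill = .data$band)) +
      ggplot2::geom_tile(color = "grey30") +
      band_fill +
      ggplot2::labs(x = NULL, y = NULL,
                    title = paste0(object$focus$kind, " card: ",
                                   object$focus$key)) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }
}

#' Plot per-database content statistics
#'
#' @param corpus A `c2_corpus`.
#' @return A ggplot bar chart of genes / EC numbers / reactions / pathways
#'   per source database.
#' @export
plot_corpus_stats <- function(corpus) {
  d <- corpus_stats(corpus) %>%
    tidyr::pivot_longer(-"source_db", names_to = "entity",
                        values_to = "n")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$source_db, y = .data$n,
                                  fill = .data$entity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "distinct entities") +
    ggplot2::theme_minimal()
}
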