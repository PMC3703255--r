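#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a card into its row table
#'
#' @param x A `c2_card`.
#' @param ... Unused.
#' @return The card's row tibble (one row per reaction-pathway-database),
#'   with the focus kind and key as columns.
#' @export
tidy.c2_card <- function(x, ...) {
  x$rows %>%
    mutate(focus_kind = x$focus$kind, focus_key = x$focus$key,
           .before = 1)
}

#' One-row consensus summary of a card
#'
#' @param x A `c2_card`.
#' @param ... Unused.
#' @return A one-row tibble: focus, number of databases and rows, number of
#'   distinct reactions, distinct EC numbers and gene renderings, and the
#'   minimum / mean displayed overlap across the card's similarity table
#'   (`NA` when fewer than two reactions are on the card).
#' @export
glance.c2_card <- function(x, ...) {
  sim_pct <- if (nrow(x$similarity)) {
    if ("percent_display" %in% names(x$similarity)) {
      x$similarity$percent_display
    } else x$similarity$percent
  } else numeric()
  non_missing <- function(v) dplyr::n_distinct(v[v != C2_MISSING])
  tibble(
    focus_kind = x$focus$kind,
    focus_key = x$focus$key,
    n_databases = dplyr::n_distinct(x$rows$source_db),
    n_rows = nrow(x$rows),
    n_reactions = dplyr::n_distinct(rec_key(x$rows$source_db,
                                            x$rows$reaction_id)),
    n_ec = non_missing(x$rows$ec),
    n_gene_renderings = non_missing(x$rows$genes),
    min_overlap = if (length(sim_pct)) min(sim_pct) else NA_real_,
    mean_overlap = if (length(sim_pct)) mean(sim_pct) else NA_real_)
}

#' Tidy a corpus into a per-database summary
#'
#' @param x A `c2_corpus`.
#' @param ... Unused.
#' @return The [corpus_stats()] tibble.
#' @export
tidy.c2_corpus <- function(x, ...) corpus_stats(x)

#' @export
glance.c2_corpus <- function(x, ...) {
  tibble(n_databases = nrow(x$databases),
         n_metabolites = nrow(x$metabolites),
         n_genes = nrow(x$genes),
         n_reactions = nrow(x$reactions),
         n_pathways = nrow(x$pathways))
}
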