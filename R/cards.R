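# ---- consensus-and-conflict cards -------------------------------------------
#
# A card is a focal entity (gene, EC number, or reaction) plus one row per
# (reaction, pathway, database) describing how each source database states
# the corresponding chemistry, with explicit reaction-similarity annotations:
# an all-pairs table for the gene/EC perspectives, per-row percent against
# the focus for the reaction perspective.

new_card <- function(kind, key, rows, similarity, id_panels, ec_panels) {
  structure(list(focus = list(kind = kind, key = key),
                 rows = rows, similarity = similarity,
                 id_panels = id_panels, ec_panels = ec_panels),
            class = "c2_card")
}

#' @export
print.c2_card <- function(x, ...) {
  cat("<c2_card: ", x$focus$kind, " perspective, focus '", x$focus$key, "'>\n",
      sep = "")
  print(x$rows, n = 20)
  invisible(x)
}

empty_card_rows <- function() {
  tibble(source_db = character(), reaction_id = character(),
         reaction = character(), overlap = character(), ec = character(),
         genes = character(), pathway = character(), link = character())
}

# one rendered row per (reaction, pathway); reactions in no pathway get one
# row with the missing marker
card_rows_for <- function(corpus, rxns, overlap_display = NULL) {
  if (nrow(rxns) == 0L) return(empty_card_rows())
  gene_sym <- setNames(gene_display_symbol(corpus$genes),
                       rec_key(corpus$genes$source_db, corpus$genes$local_id))
  url_of <- setNames(corpus$databases$url_template, corpus$databases$source_db)

  rows <- purrr::map_dfr(seq_len(nrow(rxns)), function(i) {
    db <- rxns$source_db[i]; rid <- rxns$local_id[i]
    ecs <- corpus$reaction_ec %>%
      filter(.data$source_db == db, .data$reaction_id == rid) %>% pull("ec")
    rg <- corpus$reaction_genes %>%
      filter(.data$source_db == db, .data$reaction_id == rid)
    genes_txt <- if (nrow(rg)) {
      assoc <- parse_gene_association(rg$association_text[1], rg$dialect[1])
      render_gene_association(assoc, display = function(leaf) {
        sym <- unname(gene_sym[rec_key(db, leaf)])
        ifelse(is.na(sym), leaf, sym)
      })
    } else C2_MISSING
    pw <- corpus$reaction_pathways %>%
      filter(.data$source_db == db, .data$reaction_id == rid) %>%
      left_join(corpus$pathways, by = c("source_db", "pathway_id")) %>%
      mutate(label = dplyr::coalesce(.data$name, .data$pathway_id)) %>%
      pull("label")
    if (length(pw) == 0L) pw <- C2_MISSING
    link <- if (!is.na(url_of[[db]])) {
      gsub("{id}", rid, url_of[[db]], fixed = TRUE)
    } else C2_MISSING
    tibble(source_db = db, reaction_id = rid,
           reaction = render_reaction_text(corpus, db, rid),
           overlap = if (is.null(overlap_display)) NA_character_ else
             as.character(overlap_display[[rec_key(db, rid)]]),
           ec = if (length(ecs)) paste(sort(unique(ecs)), collapse = ", ")
                else C2_MISSING,
           genes = genes_txt,
           pathway = sort(pw),
           link = link)
  })
  # canonical card ordering: database (corpus order), reaction, pathway
  db_rank <- match(rows$source_db, corpus$databases$source_db)
  rows[order(db_rank, rows$reaction_id, rows$pathway, method = "radix"), ]
}

# reaction as printed on a card: primary names, compartments in brackets,
# direction arrow
render_reaction_text <- function(corpus, db, rid) {
  rxn <- corpus$reactions %>%
    filter(.data$source_db == db, .data$local_id == rid)
  if (nrow(rxn) == 0L) abort(paste0("unknown reaction ", rec_key(db, rid)),
                             class = "c2_not_found")
  pa <- corpus$participants %>%
    filter(.data$source_db == db, .data$reaction_id == rid) %>%
    left_join(corpus$metabolites %>% select("source_db", "local_id",
                                            "primary_name"),
              by = c("source_db", "metabolite_id" = "local_id")) %>%
    mutate(label = paste0(dplyr::coalesce(.data$primary_name,
                                          .data$metabolite_id),
                          ifelse(is.na(.data$compartment), "",
                                 paste0("[", .data$compartment, "]"))))
  side_txt <- function(s) {
    paste(pa$label[pa$side == s], collapse = " + ")
  }
  paste(side_txt("left"), unname(C2_ARROWS[rxn$direction[1]]), side_txt("right"))
}

# identifier detail panels for every gene and metabolite on a set of reactions
card_id_panels <- function(corpus, rxns) {
  if (nrow(rxns) == 0L) {
    return(list(metabolites = corpus$metabolites[0, ], genes = corpus$genes[0, ]))
  }
  keys <- rec_key(rxns$source_db, rxns$local_id)
  pa <- corpus$participants %>%
    filter(rec_key(.data$source_db, .data$reaction_id) %in% keys)
  mets <- corpus$metabolites %>%
    filter(rec_key(.data$source_db, .data$local_id) %in%
             unique(rec_key(pa$source_db, pa$metabolite_id)))
  rg <- corpus$reaction_genes %>%
    filter(rec_key(.data$source_db, .data$reaction_id) %in% keys)
  gkeys <- character()
  if (nrow(rg)) {
    gkeys <- unlist(lapply(seq_len(nrow(rg)), function(i) {
      rec_key(rg$source_db[i],
              assoc_leaves(parse_gene_association(rg$association_text[i],
                                                  rg$dialect[i])))
    }))
  }
  genes <- corpus$genes %>%
    filter(rec_key(.data$source_db, .data$local_id) %in% unique(gkeys))
  list(metabolites = mets, genes = genes)
}

card_ec_panels <- function(corpus, rxns) {
  if (nrow(rxns) == 0L || nrow(corpus$ec_reference) == 0L) {
    return(corpus$ec_reference[0, ])
  }
  keys <- rec_key(rxns$source_db, rxns$local_id)
  ecs <- corpus$reaction_ec %>%
    filter(rec_key(.data$source_db, .data$reaction_id) %in% keys) %>%
    pull("ec") %>% unique()
  corpus$ec_reference %>% filter(.data$ec %in% ecs)
}

# all-pairs similarity table restricted to the card's reactions
card_similarity_all_pairs <- function(corpus, rxns, exclusion) {
  if (nrow(rxns) < 2L) {
    return(all_pairwise(corpus, sparse = FALSE, exclusion = exclusion)[0, ])
  }
  keys <- rec_key(rxns$source_db, rxns$local_id)
  all_pairwise(corpus, sparse = FALSE, exclusion = exclusion) %>%
    filter(rec_key(.data$db1, .data$reaction1) %in% keys,
           rec_key(.data$db2, .data$reaction2) %in% keys)
}

# resolve a gene query (HGNC symbol, entrez, ensembl, or db:local_id) to one
# gene equivalence class; ambiguity is an error listing candidates
resolve_gene_class <- function(corpus, gene_query) {
  genes <- corpus$genes
  classes <- gene_classes(corpus)
  keys <- rec_key(genes$source_db, genes$local_id)
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    syms <- if (is.na(genes$hgnc[i])) character()
            else strsplit(genes$hgnc[i], "|", fixed = TRUE)[[1]]
    gene_query %in% c(syms, genes$entrez[i], genes$ensembl[i], keys[i],
                      genes$local_id[i])
  }, logical(1))
  if (!any(hit)) {
    abort(paste0("no gene matches query '", gene_query, "'"),
          class = "c2_not_found")
  }
  cls <- unique(classes$class_id[match(keys[hit],
                                       rec_key(classes$source_db,
                                               classes$local_id))])
  if (length(cls) > 1L) {
    abort(paste0("ambiguous gene query '", gene_query, "': candidates ",
                 paste(cls, collapse = ", ")),
          class = "c2_ambiguous")
  }
  cls
}

# reactions whose gene association references any member of a gene class
reactions_for_gene_class <- function(corpus, class_id) {
  classes <- gene_classes(corpus)
  members <- classes %>% filter(.data$class_id == .env$class_id)
  mkeys <- rec_key(members$source_db, members$local_id)
  rg <- corpus$reaction_genes
  if (nrow(rg) == 0L) return(corpus$reactions[0, c("source_db", "local_id")])
  hit <- vapply(seq_len(nrow(rg)), function(i) {
    leaves <- assoc_leaves(parse_gene_association(rg$association_text[i],
                                                  rg$dialect[i]))
    any(rec_key(rg$source_db[i], leaves) %in% mkeys)
  }, logical(1))
  rg[hit, ] %>%
    transmute(source_db = .data$source_db, local_id = .data$reaction_id) %>%
    distinct()
}

#' Gene-perspective card
#'
#' Shows, for each source database, which metabolic functions the product
#' of a gene has: every reaction whose gene association references any
#' member of the gene's cross-database equivalence class, with that
#' database's EC and pathway context, plus an all-pairs reaction-similarity
#' table.
#'
#' @param corpus A `c2_corpus`.
#' @param gene_query HGNC symbol, Entrez or Ensembl id, or `db:local_id`
#'   key. Must resolve to exactly one gene equivalence class; an ambiguous
#'   symbol aborts listing the candidate classes.
#' @param exclusion Excluded metabolite class ids.
#' @return A `c2_card`.
#' @export
gene_card <- function(corpus, gene_query,
                      exclusion = default_exclusion_classes(corpus)) {
  cls <- resolve_gene_class(corpus, gene_query)
  rxns <- reactions_for_gene_class(corpus, cls)
  new_card("gene", cls,
           card_rows_for(corpus, rxns),
           card_similarity_all_pairs(corpus, rxns, exclusion),
           card_id_panels(corpus, rxns),
           card_ec_panels(corpus, rxns))
}

#' EC-number-perspective card
#'
#' Shows on which elements linked to an EC number the databases (dis)agree:
#' every reaction linked to a literally equal EC number (or, with
#' `fourth_wildcard`, equal in the first three components), with an
#' all-pairs similarity table.
#'
#' @param corpus A `c2_corpus`.
#' @param ec EC number text, e.g. `"6.2.1.4"`.
#' @param fourth_wildcard Also accept reactions whose EC differs only in
#'   the fourth component (default `FALSE`).
#' @param exclusion Excluded metabolite class ids.
#' @return A `c2_card` (empty rows if the EC is absent from the corpus).
#' @export
ec_card <- function(corpus, ec, fourth_wildcard = FALSE,
                    exclusion = default_exclusion_classes(corpus)) {
  focus <- ec_canonical(ec)
  links <- corpus$reaction_ec %>% filter(.data$ec_status != "obsolete")
  keep <- if (nrow(links) == 0L) logical() else if (fourth_wildcard) {
    ec_equal(links$ec, focus) | ec_family_equal(links$ec, focus)
  } else {
    ec_equal(links$ec, focus)
  }
  rxns <- links[keep, ] %>%
    transmute(source_db = .data$source_db, local_id = .data$reaction_id) %>%
    distinct()
  new_card("ec", focus,
           card_rows_for(corpus, rxns),
           card_similarity_all_pairs(corpus, rxns, exclusion),
           card_id_panels(corpus, rxns),
           card_ec_panels(corpus, rxns))
}

#' Reaction-perspective card
#'
#' Shows which gene(s) and EC number(s) each database links to a reaction
#' of interest. Rows cover the focus reaction's exact-match class and, when
#' a mismatch budget is given, near matches; each row is annotated with its
#' displayed overlap against the focus.
#'
#' @param corpus A `c2_corpus`.
#' @param reaction Either a `db:local_id` reaction key, or a reaction query
#'   (text or left/right list, see [query_reactions()]).
#' @param allowed_mismatches Mismatch budget (default 0: the exact-match
#'   class only).
#' @param exclusion Excluded metabolite class ids.
#' @return A `c2_card` whose rows carry `overlap` (display percent vs the
#'   focus) and whose `similarity` tibble holds the per-row overlap results.
#' @export
reaction_card <- function(corpus, reaction, allowed_mismatches = 0L,
                          exclusion = default_exclusion_classes(corpus)) {
  met_classes <- metabolite_classes(corpus)
  rxn_keys <- rec_key(corpus$reactions$source_db, corpus$reactions$local_id)
  if (is.character(reaction) && length(reaction) == 1L &&
      reaction %in% rxn_keys) {
    i <- match(reaction, rxn_keys)
    qsig <- make_signature(corpus, corpus$reactions$source_db[i],
                           corpus$reactions$local_id[i],
                           met_classes, exclusion)
    focus_key <- reaction
  } else {
    qs <- query_signature(corpus, reaction, met_classes, exclusion)
    if (qs$signature$size == 0L) {
      abort("reaction query resolved to an empty signature",
            class = "c2_not_found")
    }
    qsig <- qs$signature
    focus_key <- if (is.character(reaction)) reaction else
      paste(c(reaction$left, "/", reaction$right), collapse = " ")
  }
  sim <- query_reactions_sig(corpus, qsig, allowed_mismatches, exclusion)
  rxns <- sim %>% select("source_db", "local_id")
  ov <- setNames(as.list(sim$percent_display),
                 rec_key(sim$source_db, sim$local_id))
  new_card("reaction", focus_key,
           card_rows_for(corpus, rxns, overlap_display = ov),
           sim,
           card_id_panels(corpus, rxns),
           card_ec_panels(corpus, rxns))
}

# query_reactions against a prebuilt signature
query_reactions_sig <- function(corpus, qsig, allowed_mismatches, exclusion) {
  sig <- corpus_signatures(corpus, metabolite_classes(corpus), exclusion)
  rows <- purrr::map_dfr(seq_len(nrow(sig$sizes)), function(i) {
    s <- signature_from_long(sig$long, sig$sizes, i)
    ov <- overlap(qsig, s)
    mm <- as.integer(max(ov$size1, ov$size2) - ov$matches)
    if (mm > allowed_mismatches) return(NULL)
    tibble(source_db = s$source_db, local_id = s$local_id,
           percent = ov$percent, percent_display = display_percent(ov$percent),
           matches = ov$matches, size1 = ov$size1, size2 = ov$size2,
           orientation = ov$orientation, mismatches = mm)
  })
  if (nrow(rows) == 0L) {
    return(tibble(source_db = character(), local_id = character(),
                  percent = numeric(), percent_display = integer(),
                  matches = integer(), size1 = integer(), size2 = integer(),
                  orientation = character(), mismatches = integer()))
  }
  rows %>% arrange(dplyr::desc(.data$percent), .data$source_db, .data$local_id)
}
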