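# ---- corpus-level utilities -------------------------------------------------

#' Dead-end metabolites of one database
#'
#' Within one database, a metabolite class is a dead-end if it is either
#' only produced or only consumed by that database's reactions. A forward
#' reaction consumes its left side and produces its right side; reversible
#' and unknown-direction reactions count as both producing and consuming
#' every participant (absence of direction evidence should not create
#' spurious dead-ends). By default the currency-metabolite exclusion list
#' applies (e-, H+, H2O are not meaningful dead-ends); set
#' `apply_exclusion = FALSE` to assess every class.
#'
#' @param corpus A `c2_corpus`.
#' @param db Source database label.
#' @param apply_exclusion Apply the currency exclusion list (default `TRUE`).
#' @param exclusion Excluded class ids when `apply_exclusion` is `TRUE`.
#' @return A tibble `(source_db, class_id, status, witness_reactions)` with
#'   status `produced_only` or `consumed_only`; `witness_reactions` is a
#'   `|`-joined list of the reactions the class appears in.
#' @export
dead_end_metabolites <- function(corpus, db, apply_exclusion = TRUE,
                                 exclusion = default_exclusion_classes(corpus)) {
  if (!db %in% corpus$databases$source_db) {
    abort(paste0("unknown database: ", db), class = "c2_not_found")
  }
  met_classes <- metabolite_classes(corpus)
  cls_of <- setNames(met_classes$class_id,
                     rec_key(met_classes$source_db, met_classes$local_id))
  pa <- corpus$participants %>% filter(.data$source_db == db)
  if (nrow(pa) == 0L) {
    return(tibble(source_db = character(), class_id = character(),
                  status = character(), witness_reactions = character()))
  }
  dir_of <- setNames(corpus$reactions$direction,
                     rec_key(corpus$reactions$source_db,
                             corpus$reactions$local_id))
  tbl <- pa %>%
    mutate(class_id = unname(cls_of[rec_key(.data$source_db,
                                            .data$metabolite_id)]),
           direction = unname(dir_of[rec_key(.data$source_db,
                                             .data$reaction_id)]),
           consumed = .data$direction != "forward" | .data$side == "left",
           produced = .data$direction != "forward" | .data$side == "right")
  if (apply_exclusion) tbl <- tbl %>% filter(!.data$class_id %in% exclusion)
  if (nrow(tbl) == 0L) {
    return(tibble(source_db = character(), class_id = character(),
                  status = character(), witness_reactions = character()))
  }
  tbl %>%
    group_by(.data$class_id) %>%
    summarise(consumed = any(.data$consumed), produced = any(.data$produced),
              witness_reactions = paste(sort(unique(.data$reaction_id)),
                                        collapse = "|"),
              .groups = "drop") %>%
    filter(xor(.data$consumed, .data$produced)) %>%
    transmute(source_db = db, class_id = .data$class_id,
              status = if_else(.data$produced, "produced_only",
                               "consumed_only"),
              witness_reactions = .data$witness_reactions) %>%
    arrange(.data$class_id)
}

#' Fate of a metabolite across databases
#'
#' Resolves the query to a metabolite equivalence class and lists, for each
#' database, every reaction in which any class member participates.
#' Databases in which the metabolite is a dead-end are flagged.
#'
#' @param corpus A `c2_corpus`.
#' @param metabolite_query Name, synonym, identifier, or `db:local_id` key.
#' @param apply_exclusion,exclusion Passed to [dead_end_metabolites()].
#' @return A tibble `(source_db, local_id, reaction, dead_end, dead_end_status)`
#'   with one row per (database, reaction); databases not containing the
#'   metabolite contribute no rows.
#' @export
metabolite_fate <- function(corpus, metabolite_query, apply_exclusion = TRUE,
                            exclusion = default_exclusion_classes(corpus)) {
  met_classes <- metabolite_classes(corpus)
  cls <- resolve_metabolite_term(corpus, metabolite_query, met_classes)
  if (length(cls) == 0L) {
    abort(paste0("no metabolite matches query '", metabolite_query, "'"),
          class = "c2_not_found")
  }
  if (length(cls) > 1L) {
    warn(paste0("query '", metabolite_query, "' matches ", length(cls),
                " metabolite classes; using all"))
  }
  members <- met_classes %>% filter(.data$class_id %in% cls)
  mkeys <- rec_key(members$source_db, members$local_id)
  hits <- corpus$participants %>%
    filter(rec_key(.data$source_db, .data$metabolite_id) %in% mkeys) %>%
    distinct(.data$source_db, local_id = .data$reaction_id)
  if (nrow(hits) == 0L) return(tibble(source_db = character(),
                                      local_id = character(),
                                      reaction = character(),
                                      dead_end = logical(),
                                      dead_end_status = character()))
  de <- purrr::map_dfr(unique(hits$source_db), function(db) {
    dead_end_metabolites(corpus, db, apply_exclusion, exclusion) %>%
      filter(.data$class_id %in% cls) %>%
      transmute(source_db = db, dead_end_status = .data$status)
  })
  hits %>%
    mutate(reaction = purrr::map2_chr(.data$source_db, .data$local_id,
                                      ~render_reaction_text(corpus, .x, .y))) %>%
    left_join(de, by = "source_db") %>%
    mutate(dead_end = !is.na(.data$dead_end_status)) %>%
    arrange(.data$source_db, .data$local_id)
}

#' Pathway membership tables
#'
#' Links the genes and metabolites of each database to the pathways their
#' reactions belong to — the inputs a pathway-enrichment analysis needs.
#' One row per (database, entity, pathway); entities whose reactions are in
#' no pathway contribute no rows. The currency exclusion list is *not*
#' applied here.
#'
#' @param corpus A `c2_corpus`.
#' @return A list of two tibbles: `genes` `(source_db, gene_id, pathway_id,
#'   pathway_name)` and `metabolites` `(source_db, metabolite_id,
#'   pathway_id, pathway_name)`.
#' @export
pathway_membership_tables <- function(corpus) {
  rp <- corpus$reaction_pathways %>%
    left_join(corpus$pathways, by = c("source_db", "pathway_id")) %>%
    rename(pathway_name = "name")
  met <- corpus$participants %>%
    inner_join(rp, by = c("source_db", "reaction_id"),
               relationship = "many-to-many") %>%
    distinct(.data$source_db, metabolite_id = .data$metabolite_id,
             .data$pathway_id, .data$pathway_name) %>%
    arrange(.data$source_db, .data$metabolite_id, .data$pathway_id)
  rg <- corpus$reaction_genes
  gene_links <- if (nrow(rg)) {
    purrr::map_dfr(seq_len(nrow(rg)), function(i) {
      tibble(source_db = rg$source_db[i], reaction_id = rg$reaction_id[i],
             gene_id = assoc_leaves(parse_gene_association(
               rg$association_text[i], rg$dialect[i])))
    })
  } else tibble(source_db = character(), reaction_id = character(),
                gene_id = character())
  gen <- gene_links %>%
    inner_join(rp, by = c("source_db", "reaction_id"),
               relationship = "many-to-many") %>%
    distinct(.data$source_db, .data$gene_id, .data$pathway_id,
             .data$pathway_name) %>%
    arrange(.data$source_db, .data$gene_id, .data$pathway_id)
  list(genes = gen, metabolites = met)
}

#' Per-database content statistics
#'
#' Distinct-entity counts per source database: genes, EC numbers (distinct
#' EC texts linked to any reaction), reactions, pathways.
#'
#' @param corpus A `c2_corpus`.
#' @return A tibble `(source_db, genes, ec_numbers, reactions, pathways)`,
#'   one row per database (zeros for empty databases).
#' @export
corpus_stats <- function(corpus) {
  dbs <- corpus$databases %>% select("source_db")
  cnt <- function(tbl, col) {
    tbl %>% distinct(.data$source_db, .data[[col]]) %>%
      count(.data$source_db, name = "n")
  }
  dbs %>%
    left_join(cnt(corpus$genes, "local_id") %>% rename(genes = "n"),
              by = "source_db") %>%
    left_join(cnt(corpus$reaction_ec, "ec") %>% rename(ec_numbers = "n"),
              by = "source_db") %>%
    left_join(cnt(corpus$reactions, "local_id") %>% rename(reactions = "n"),
              by = "source_db") %>%
    left_join(cnt(corpus$pathways, "pathway_id") %>% rename(pathways = "n"),
              by = "source_db") %>%
    mutate(across(c("genes", "ec_numbers", "reactions", "pathways"),
                  ~dplyr::coalesce(.x, 0L))) %>%
    arrange(.data$source_db)
}

#' Cross-database presence overview
#'
#' For each entity kind, a boolean matrix of equivalence class (or EC text)
#' by database: which genes, metabolites, EC numbers and reactions can be
#' found in which database. Reaction presence uses exact-match (100%
#' overlap) classes, so near-duplicates stay on separate rows.
#'
#' @param corpus A `c2_corpus`.
#' @param kinds Subset of `c("gene", "metabolite", "ec", "reaction")`.
#' @return A named list of wide tibbles, each with a `class_id` column and
#'   one logical column per database.
#' @export
presence_overview <- function(corpus,
                              kinds = c("gene", "metabolite", "ec", "reaction")) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  dbs <- corpus$databases$source_db
  widen <- function(long) {
    if (nrow(long) == 0L) {
      out <- tibble(class_id = character())
      for (db in dbs) out[[db]] <- logical()
      return(out)
    }
    wide <- long %>%
      distinct(.data$class_id, .data$source_db) %>%
      mutate(present = TRUE) %>%
      tidyr::pivot_wider(names_from = "source_db", values_from = "present",
                         values_fill = FALSE)
    for (db in setdiff(dbs, names(wide))) wide[[db]] <- FALSE
    wide %>% select(all_of(c("class_id", dbs))) %>% arrange(.data$class_id)
  }
  out <- list()
  if ("gene" %in% kinds) out$gene <- widen(gene_classes(corpus))
  if ("metabolite" %in% kinds) out$metabolite <- widen(metabolite_classes(corpus))
  if ("ec" %in% kinds) {
    out$ec <- widen(corpus$reaction_ec %>%
                      transmute(class_id = .data$ec, .data$source_db))
  }
  if ("reaction" %in% kinds) out$reaction <- widen(exact_reaction_classes(corpus))
  out
}
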