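# ---- pairwise matching rules ------------------------------------------------

# identifier usable for matching: present and not flagged obsolete
usable_id <- function(record, ns) {
  v <- record[[ns]]
  st <- record[[paste0(ns, "_status")]]
  if (is.null(v) || is.na(v)) return(NA_character_)
  if (!is.null(st) && !is.na(st) && st == "obsolete") return(NA_character_)
  v
}

# all normalized name keys of a metabolite record (primary + synonyms)
met_name_keys <- function(record) {
  nm <- c(record$primary_name,
          if (!is.null(record$synonyms) && !is.na(record$synonyms))
            strsplit(record$synonyms, "|", fixed = TRUE)[[1]])
  keys <- normalize_name(nm[!is.na(nm)])
  unique(keys[nzchar(keys)])
}

#' Pairwise metabolite match
#'
#' The decision cascade: (1) if both records carry a KEGG Compound id, they
#' match iff the ids are equal and the cascade stops — a KEGG Compound
#' disagreement can never be overridden by other evidence; (2) otherwise any
#' of KEGG Glycan, ChEBI, PubChem Compound or CAS present in both and equal
#' is a match; (3) otherwise a name match (any primary name or synonym of
#' one against any of the other, case/space/punctuation-insensitive)
#' combined with a hydrogen-insensitive chemical-formula match is a match.
#' Identifiers flagged obsolete are excluded from every step; name matching
#' requires a parseable formula on both sides.
#'
#' @param m1,m2 Single-row data frames (or lists) in the metabolites schema.
#' @return `TRUE` or `FALSE`.
#' @export
metabolite_pair_match <- function(m1, m2) {
  k1 <- usable_id(m1, "kegg_compound")
  k2 <- usable_id(m2, "kegg_compound")
  if (!is.na(k1) && !is.na(k2)) return(k1 == k2)
  for (ns in c("kegg_glycan", "chebi", "pubchem_compound", "cas")) {
    v1 <- usable_id(m1, ns)
    v2 <- usable_id(m2, ns)
    if (!is.na(v1) && !is.na(v2) && v1 == v2) return(TRUE)
  }
  if (length(intersect(met_name_keys(m1), met_name_keys(m2))) > 0L) {
    f1 <- parse_formula(if (is.null(m1$formula)) NA_character_ else m1$formula)
    f2 <- parse_formula(if (is.null(m2$formula)) NA_character_ else m2$formula)
    if (!is.null(f1) && !is.null(f2) && formulas_match(f1, f2)) return(TRUE)
  }
  FALSE
}

#' Pairwise gene match
#'
#' Two genes match if they agree on the Entrez Gene id and/or the Ensembl
#' Gene id. Genes not linked to the same genome database (one record has
#' only Entrez, the other only Ensembl) can still be matched via a shared
#' HGNC symbol; this fallback applies only when the records share no id
#' namespace, so it never overrides an explicit id disagreement. Obsolete
#' identifiers are excluded.
#'
#' @param g1,g2 Single-row data frames (or lists) in the genes schema.
#' @return `TRUE` or `FALSE`.
#' @export
gene_pair_match <- function(g1, g2) {
  e1 <- usable_id(g1, "entrez");  e2 <- usable_id(g2, "entrez")
  n1 <- usable_id(g1, "ensembl"); n2 <- usable_id(g2, "ensembl")
  if (!is.na(e1) && !is.na(e2) && e1 == e2) return(TRUE)
  if (!is.na(n1) && !is.na(n2) && n1 == n2) return(TRUE)
  shared_ns <- (!is.na(e1) && !is.na(e2)) || (!is.na(n1) && !is.na(n2))
  if (shared_ns) return(FALSE)
  h <- function(g) {
    if (is.null(g$hgnc) || is.na(g$hgnc)) return(character())
    strsplit(g$hgnc, "|", fixed = TRUE)[[1]]
  }
  length(intersect(h(g1), h(g2))) > 0L
}

# ---- transitive closure -----------------------------------------------------

#' Transitive-closure equivalence classes from a pairwise rule
#'
#' A match between databases A and B and one between B and C makes the
#' entity match between A and C as well: classes are the connected
#' components of the pairwise match graph. Class ids are deterministic —
#' the lexicographically smallest `(source_db, local_id)` member key.
#'
#' @param records A tibble with `source_db` and `local_id` columns.
#' @param pair_rule Symmetric predicate taking two single-row records.
#' @return A tibble `(class_id, source_db, local_id)`, one row per record.
#' @export
build_equivalence <- function(records, pair_rule) {
  records <- as_tibble(records)
  n <- nrow(records)
  edges <- NULL
  if (n > 1L) {
    rows <- split(records, seq_len(n))
    hits <- list()
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (isTRUE(pair_rule(rows[[i]], rows[[j]]))) {
          hits[[length(hits) + 1L]] <- c(i, j)
        }
      }
    }
    if (length(hits)) edges <- do.call(rbind, hits)
  }
  components_to_classes(records, edges)
}

# connected components over record indices; edges is a 2-col index matrix
components_to_classes <- function(records, edges) {
  n <- nrow(records)
  if (n == 0L) {
    return(tibble(class_id = character(), source_db = character(),
                  local_id = character()))
  }
  membership <- if (is.null(edges) || nrow(edges) == 0L) {
    seq_len(n)
  } else {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    igraph::components(g)$membership
  }
  keys <- rec_key(records$source_db, records$local_id)
  # smallest member key per component, by (source_db, local_id) order
  ord <- order(records$source_db, records$local_id, method = "radix")
  first_of <- tapply(ord, membership[ord], function(ix) ix[1])
  class_of <- keys[first_of[as.character(membership)]]
  tibble(class_id = unname(class_of),
         source_db = records$source_db,
         local_id = records$local_id) %>%
    arrange(.data$class_id, .data$source_db, .data$local_id)
}

# join-based edge construction for metabolites, equivalent to the pairwise
# cascade but near-linear in record count
metabolite_edges <- function(mets) {
  n <- nrow(mets)
  if (n < 2L) return(NULL)
  idx <- tibble(i = seq_len(n))
  live <- function(ns) {
    v <- mets[[ns]]
    st <- mets[[paste0(ns, "_status")]]
    ifelse(!is.na(v) & st != "obsolete", v, NA_character_)
  }
  kegg <- live("kegg_compound")
  pairs_on <- function(values) {
    d <- tibble(i = seq_len(n), v = values) %>% filter(!is.na(.data$v))
    if (nrow(d) < 2L) return(NULL)
    e <- inner_join(d, d, by = "v", relationship = "many-to-many") %>%
      filter(.data$i.x < .data$i.y)
    if (nrow(e)) cbind(e$i.x, e$i.y) else NULL
  }
  both_kegg <- function(e) !is.na(kegg[e[, 1]]) & !is.na(kegg[e[, 2]])
  edges <- list()
  # step 1: shared KEGG Compound
  e1 <- pairs_on(kegg)
  if (!is.null(e1)) edges <- c(edges, list(e1))
  # step 2: other identifiers, unless both records carry KEGG Compound
  for (ns in c("kegg_glycan", "chebi", "pubchem_compound", "cas")) {
    e <- pairs_on(live(ns))
    if (!is.null(e)) {
      e <- e[!both_kegg(e), , drop = FALSE]
      if (nrow(e)) edges <- c(edges, list(e))
    }
  }
  # step 3: name + formula, unless both records carry KEGG Compound
  name_tbl <- purrr::map_dfr(seq_len(n), function(i) {
    keys <- met_name_keys(mets[i, ])
    if (length(keys)) tibble(i = i, key = keys) else NULL
  })
  if (nrow(name_tbl) >= 2L) {
    e <- inner_join(name_tbl, name_tbl, by = "key",
                    relationship = "many-to-many") %>%
      filter(.data$i.x < .data$i.y) %>%
      distinct(.data$i.x, .data$i.y)
    if (nrow(e)) {
      keep <- !(!is.na(kegg[e$i.x]) & !is.na(kegg[e$i.y])) &
        formulas_match_chr(mets$formula[e$i.x], mets$formula[e$i.y])
      e <- e[keep, , drop = FALSE]
      if (nrow(e)) edges <- c(edges, list(cbind(e$i.x, e$i.y)))
    }
  }
  if (length(edges)) unique(do.call(rbind, edges)) else NULL
}

gene_edges <- function(genes) {
  n <- nrow(genes)
  if (n < 2L) return(NULL)
  live <- function(ns) {
    v <- genes[[ns]]
    st <- genes[[paste0(ns, "_status")]]
    ifelse(!is.na(v) & st != "obsolete", v, NA_character_)
  }
  entrez <- live("entrez"); ensembl <- live("ensembl")
  pairs_on <- function(values) {
    d <- tibble(i = seq_len(n), v = values) %>% filter(!is.na(.data$v))
    if (nrow(d) < 2L) return(NULL)
    e <- inner_join(d, d, by = "v", relationship = "many-to-many") %>%
      filter(.data$i.x < .data$i.y)
    if (nrow(e)) cbind(e$i.x, e$i.y) else NULL
  }
  edges <- list()
  for (v in list(entrez, ensembl)) {
    e <- pairs_on(v)
    if (!is.null(e)) edges <- c(edges, list(e))
  }
  # HGNC fallback: only for pairs sharing no id namespace
  hg <- purrr::map_dfr(seq_len(n), function(i) {
    if (is.na(genes$hgnc[i])) return(NULL)
    tibble(i = i, sym = strsplit(genes$hgnc[i], "|", fixed = TRUE)[[1]])
  })
  if (nrow(hg) >= 2L) {
    e <- inner_join(hg, hg, by = "sym", relationship = "many-to-many") %>%
      filter(.data$i.x < .data$i.y) %>%
      distinct(.data$i.x, .data$i.y)
    if (nrow(e)) {
      shared <- (!is.na(entrez[e$i.x]) & !is.na(entrez[e$i.y])) |
        (!is.na(ensembl[e$i.x]) & !is.na(ensembl[e$i.y]))
      e <- e[!shared, , drop = FALSE]
      if (nrow(e)) edges <- c(edges, list(cbind(e$i.x, e$i.y)))
    }
  }
  if (length(edges)) unique(do.call(rbind, edges)) else NULL
}

#' Cross-database metabolite equivalence classes
#'
#' Applies the pairwise metabolite cascade to every pair of metabolite
#' records in the corpus (within and across databases) and takes the
#' transitive closure. Cached on the corpus.
#'
#' @param corpus A `c2_corpus`.
#' @return A tibble `(class_id, source_db, local_id)`.
#' @export
metabolite_classes <- function(corpus) {
  cached(corpus, "met_classes", function() {
    components_to_classes(corpus$metabolites, metabolite_edges(corpus$metabolites))
  })
}

#' Cross-database gene equivalence classes
#'
#' Pairwise gene matching (Entrez/Ensembl agreement, HGNC fallback) followed
#' by transitive closure. Cached on the corpus.
#'
#' @inheritParams metabolite_classes
#' @return A tibble `(class_id, source_db, local_id)`.
#' @export
gene_classes <- function(corpus) {
  cached(corpus, "gene_classes", function() {
    components_to_classes(corpus$genes, gene_edges(corpus$genes))
  })
}

#' Export equivalence classes as TSV
#'
#' @param classes A classes tibble from [metabolite_classes()],
#'   [gene_classes()], [exact_reaction_classes()] or [build_equivalence()].
#' @param kind Entity kind label written in the first column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_equivalence <- function(classes, kind, path) {
  out <- tibble(kind = kind, class_id = classes$class_id,
                source_db = classes$source_db, local_id = classes$local_id)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
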