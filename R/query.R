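# ---- all-pairs overlap, exact classes, tolerant queries ---------------------

#' All-pairs reaction overlap matrix
#'
#' Computes the percentage of overlap between every unordered pair of
#' reactions in the corpus via joins on the signature table (near-linear in
#' the number of shared classes). By default only pairs with at least one
#' matching metabolite are stored (`sparse = TRUE`); dense mode emits all
#' n(n-1)/2 pairs.
#'
#' @param corpus A `c2_corpus`.
#' @param sparse Drop pairs with zero matches (default `TRUE`).
#' @param exclusion Excluded class ids (default
#'   [default_exclusion_classes()]).
#' @return A tibble `(db1, reaction1, db2, reaction2, percent,
#'   percent_display, matches, size1, size2, orientation)`, symmetric by
#'   construction with the pair stored once (key1 < key2).
#' @export
all_pairwise <- function(corpus, sparse = TRUE,
                         exclusion = default_exclusion_classes(corpus)) {
  sig <- corpus_signatures(corpus, exclusion = exclusion)
  long <- sig$long %>% mutate(key = rec_key(.data$source_db, .data$local_id))
  sizes <- sig$sizes %>% mutate(key = rec_key(.data$source_db, .data$local_id))

  count_pairs <- function(a, b) {
    inner_join(a, b, by = "class_id", relationship = "many-to-many") %>%
      filter(.data$key.x < .data$key.y) %>%
      count(.data$key.x, .data$key.y, name = "m")
  }
  ll <- long %>% select("key", "class_id", "side")
  par <- count_pairs(ll %>% filter(.data$side == "left"),
                     ll %>% filter(.data$side == "left")) %>%
    bind_rows(count_pairs(ll %>% filter(.data$side == "right"),
                          ll %>% filter(.data$side == "right"))) %>%
    count(.data$key.x, .data$key.y, wt = .data$m, name = "par")
  anti <- count_pairs(ll %>% filter(.data$side == "left"),
                      ll %>% filter(.data$side == "right") %>%
                        mutate(side = "left")) %>%
    bind_rows(count_pairs(ll %>% filter(.data$side == "right") %>%
                            mutate(side = "left"),
                          ll %>% filter(.data$side == "left"))) %>%
    count(.data$key.x, .data$key.y, wt = .data$m, name = "anti")

  pairs <- full_join(par, anti, by = c("key.x", "key.y")) %>%
    mutate(par = dplyr::coalesce(.data$par, 0L),
           anti = dplyr::coalesce(.data$anti, 0L))
  if (!sparse) {
    keys <- sort(sizes$key)
    if (length(keys) > 1L) {
      allp <- tidyr::expand_grid(key.x = keys, key.y = keys) %>%
        filter(.data$key.x < .data$key.y)
      pairs <- allp %>%
        left_join(pairs, by = c("key.x", "key.y")) %>%
        mutate(par = dplyr::coalesce(.data$par, 0L),
               anti = dplyr::coalesce(.data$anti, 0L))
    }
  }
  size_of <- setNames(sizes$size, sizes$key)
  db_of <- setNames(sizes$source_db, sizes$key)
  id_of <- setNames(sizes$local_id, sizes$key)
  out <- pairs %>%
    mutate(matches = pmax(.data$par, .data$anti),
           size1 = unname(size_of[.data$key.x]),
           size2 = unname(size_of[.data$key.y]),
           denom = pmax(.data$size1, .data$size2),
           percent = ifelse(.data$denom == 0L, 0,
                            .data$matches / .data$denom * 100),
           percent_display = display_percent(.data$percent),
           orientation = ifelse(.data$par >= .data$anti, "parallel",
                                "antiparallel"),
           db1 = unname(db_of[.data$key.x]), reaction1 = unname(id_of[.data$key.x]),
           db2 = unname(db_of[.data$key.y]), reaction2 = unname(id_of[.data$key.y])) %>%
    select("db1", "reaction1", "db2", "reaction2", "percent", "percent_display",
           "matches", "size1", "size2", "orientation") %>%
    arrange(.data$db1, .data$reaction1, .data$db2, .data$reaction2)
  if (sparse) out <- out %>% filter(.data$matches > 0L)
  out
}

#' Export an overlap matrix as TSV
#'
#' @param pairs Tibble from [all_pairwise()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_matrix <- function(pairs, path) {
  readr::write_tsv(pairs %>% select("db1", "reaction1", "db2", "reaction2",
                                    "percent_display", "matches", "size1",
                                    "size2", "orientation"),
                   path, na = "", progress = FALSE)
  invisible(path)
}

#' Exact-match reaction equivalence classes
#'
#' Transitive closure over reaction pairs with 100% overlap (equal,
#' nonempty signatures under the best orientation). Partial overlaps are
#' reported by [all_pairwise()] but never merged.
#'
#' @inheritParams all_pairwise
#' @return A tibble `(class_id, source_db, local_id)`, one row per reaction.
#' @export
exact_reaction_classes <- function(corpus,
                                   exclusion = default_exclusion_classes(corpus)) {
  pairs <- all_pairwise(corpus, sparse = TRUE, exclusion = exclusion) %>%
    filter(.data$percent == 100)
  records <- corpus$reactions %>% select("source_db", "local_id")
  keys <- rec_key(records$source_db, records$local_id)
  edges <- if (nrow(pairs)) {
    cbind(match(rec_key(pairs$db1, pairs$reaction1), keys),
          match(rec_key(pairs$db2, pairs$reaction2), keys))
  } else NULL
  components_to_classes(records, edges)
}

# ---- reaction queries -------------------------------------------------------

#' Parse a textual reaction query
#'
#' Splits `"l-arginine + H2O -> ornithine + urea"` into left/right term
#' lists. Recognized arrows: `->`, `-->`, the unicode arrow, `<==>`, `=`,
#' `<=>`, `|==|`. Compartment tags in square brackets are stripped.
#'
#' @param text Reaction query text.
#' @return List with `left` and `right` character vectors of terms.
#' @export
parse_reaction_query <- function(text) {
  sides <- stringr::str_split(text,
    "\\s*(<==>|<=>|-->|->|→|\\|==\\||(?<![<>=])=(?![<>=]))\\s*")[[1]]
  if (length(sides) != 2L) {
    abort(paste0("reaction query must have exactly two sides: '", text, "'"),
          class = "c2_parse_error")
  }
  terms <- lapply(sides, function(s) {
    t <- stringr::str_trim(strsplit(s, "+", fixed = TRUE)[[1]])
    t <- gsub("\\s*\\[[^]]*\\]\\s*$", "", t)
    t[nzchar(t)]
  })
  list(left = terms[[1]], right = terms[[2]])
}

# resolve one query term to metabolite class ids: by normalized name/synonym,
# any identifier value, or db:local_id key
resolve_metabolite_term <- function(corpus, term,
                                    met_classes = metabolite_classes(corpus)) {
  mets <- corpus$metabolites
  keys <- rec_key(mets$source_db, mets$local_id)
  nkey <- normalize_name(term)
  hit <- vapply(seq_len(nrow(mets)), function(i) {
    (nzchar(nkey) && nkey %in% met_name_keys(mets[i, ])) ||
      term == keys[i] || term == mets$local_id[i] ||
      any(!is.na(unlist(mets[i, MET_ID_NAMESPACES])) &
            unlist(mets[i, MET_ID_NAMESPACES]) == term)
  }, logical(1))
  cls <- met_classes$class_id[match(keys[hit],
                                    rec_key(met_classes$source_db,
                                            met_classes$local_id))]
  sort(unique(cls))
}

# build a query signature from side-assigned terms
query_signature <- function(corpus, query,
                            met_classes = metabolite_classes(corpus),
                            exclusion = default_exclusion_classes(corpus)) {
  if (is.character(query) && length(query) == 1L) {
    query <- parse_reaction_query(query)
  }
  stopifnot(is.list(query), all(c("left", "right") %in% names(query)))
  resolve_side <- function(terms) {
    res <- lapply(terms, resolve_metabolite_term, corpus = corpus,
                  met_classes = met_classes)
    names(res) <- terms
    res
  }
  left <- resolve_side(query$left)
  right <- resolve_side(query$right)
  unresolved <- c(names(left)[lengths(left) == 0L],
                  names(right)[lengths(right) == 0L])
  sig <- new_signature("query", "query",
                       sort(setdiff(unique(unlist(left)), exclusion)),
                       sort(setdiff(unique(unlist(right)), exclusion)))
  list(signature = sig, unresolved = unresolved,
       resolution = c(left, right))
}

#' Mismatch-tolerant reaction query
#'
#' Resolves the query's metabolite terms to equivalence classes, forms a
#' query signature, and returns every reaction whose unmatched-metabolite
#' count against the query is within the allowed budget, ranked by
#' descending overlap then reaction key.
#'
#' @param corpus A `c2_corpus`.
#' @param query Reaction text (see [parse_reaction_query()]) or a list with
#'   `left`/`right` term vectors.
#' @param allowed_mismatches Non-negative mismatch budget (default 0).
#' @param pathway_filter Optional pathway name or id; only reactions linked
#'   to a matching pathway are returned.
#' @param exclusion Excluded class ids.
#' @return A tibble `(source_db, local_id, percent, percent_display,
#'   matches, size1, size2, orientation, mismatches)` with attribute
#'   `"unresolved"` listing terms that resolved to no metabolite. If no term
#'   resolves the result is empty.
#' @export
query_reactions <- function(corpus, query, allowed_mismatches = 0L,
                            pathway_filter = NULL,
                            exclusion = default_exclusion_classes(corpus)) {
  stopifnot(allowed_mismatches >= 0L)
  met_classes <- metabolite_classes(corpus)
  qs <- query_signature(corpus, query, met_classes, exclusion)
  empty <- tibble(source_db = character(), local_id = character(),
                  percent = numeric(), percent_display = integer(),
                  matches = integer(), size1 = integer(), size2 = integer(),
                  orientation = character(), mismatches = integer())
  if (length(qs$unresolved)) {
    warn(paste0("unresolved query term(s): ",
                paste(qs$unresolved, collapse = ", ")))
  }
  if (qs$signature$size == 0L) {
    return(structure(empty, unresolved = qs$unresolved))
  }
  sig <- corpus_signatures(corpus, met_classes, exclusion)
  rows <- purrr::map_dfr(seq_len(nrow(sig$sizes)), function(i) {
    s <- signature_from_long(sig$long, sig$sizes, i)
    ov <- overlap(qs$signature, s)
    mm <- as.integer(max(ov$size1, ov$size2) - ov$matches)
    if (mm > allowed_mismatches) return(NULL)
    tibble(source_db = s$source_db, local_id = s$local_id,
           percent = ov$percent, percent_display = display_percent(ov$percent),
           matches = ov$matches, size1 = ov$size1, size2 = ov$size2,
           orientation = ov$orientation, mismatches = mm)
  })
  if (nrow(rows) == 0L) return(structure(empty, unresolved = qs$unresolved))
  if (!is.null(pathway_filter)) {
    pw <- corpus$reaction_pathways %>%
      left_join(corpus$pathways, by = c("source_db", "pathway_id")) %>%
      filter(.data$pathway_id == pathway_filter | .data$name == pathway_filter)
    rows <- rows %>%
      semi_join(pw, by = c("source_db", "local_id" = "reaction_id"))
  }
  rows <- rows %>%
    arrange(dplyr::desc(.data$percent), .data$source_db, .data$local_id)
  structure(rows, unresolved = qs$unresolved)
}
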