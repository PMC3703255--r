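# ---- reaction signatures and the percentage of overlap ----------------------

# seed name keys / KEGG ids for the currency species excluded from matching
CURRENCY_NAME_KEYS <- c("h2o", "water", "h", "proton", "hydron", "e", "electron")
CURRENCY_KEGG_IDS <- c("C00001", "C00080", "C05359")

#' Metabolite classes excluded from reaction matching
#'
#' Reactions are inconsistently balanced for electrons, protons and water
#' (pH conventions differ between databases), so the classes containing
#' e-, H+ and H2O are excluded from reaction signatures. The exclusion set
#' is seeded from well-known names and KEGG Compound ids and can be
#' extended with additional names or ids.
#'
#' @param corpus A `c2_corpus`.
#' @param extra_names,extra_ids Additional metabolite names / KEGG Compound
#'   ids whose classes should also be excluded.
#' @return Character vector of excluded metabolite class ids.
#' @export
default_exclusion_classes <- function(corpus, extra_names = character(),
                                      extra_ids = character()) {
  classes <- metabolite_classes(corpus)
  mets <- corpus$metabolites
  name_keys <- c(CURRENCY_NAME_KEYS, normalize_name(extra_names))
  ids <- c(CURRENCY_KEGG_IDS, extra_ids)
  hit <- vapply(seq_len(nrow(mets)), function(i) {
    any(met_name_keys(mets[i, ]) %in% name_keys) ||
      (!is.na(mets$kegg_compound[i]) && mets$kegg_compound[i] %in% ids)
  }, logical(1))
  if (!any(hit)) return(character())
  keys_hit <- rec_key(mets$source_db[hit], mets$local_id[hit])
  classes %>%
    filter(rec_key(.data$source_db, .data$local_id) %in% keys_hit) %>%
    pull("class_id") %>% unique() %>% sort()
}

#' Build the signature of a single reaction
#'
#' A signature is the pair of per-side sets of metabolite equivalence
#' classes, after removing the excluded (currency) classes and collapsing
#' duplicates. Compartments and stoichiometry never enter a signature.
#' An empty side after exclusion is permitted.
#'
#' @param corpus A `c2_corpus`.
#' @param source_db,local_id Reaction key.
#' @param met_classes Classes tibble (default [metabolite_classes()]).
#' @param exclusion Excluded class ids (default
#'   [default_exclusion_classes()]).
#' @return A `c2_signature`: list with `key`, `source_db`, `local_id`,
#'   `left`, `right` (class-id sets) and `size` = |left| + |right|.
#' @export
make_signature <- function(corpus, source_db, local_id,
                           met_classes = metabolite_classes(corpus),
                           exclusion = default_exclusion_classes(corpus)) {
  key <- rec_key(source_db, local_id)
  if (!key %in% rec_key(corpus$reactions$source_db, corpus$reactions$local_id)) {
    abort(paste0("unknown reaction: ", key), class = "c2_not_found")
  }
  pa <- corpus$participants %>%
    filter(.data$source_db == .env$source_db, .data$reaction_id == .env$local_id)
  cls <- met_classes$class_id[match(rec_key(pa$source_db, pa$metabolite_id),
                                    rec_key(met_classes$source_db,
                                            met_classes$local_id))]
  if (anyNA(cls)) {
    abort(paste0("unresolved participant metabolite(s) in reaction ", key),
          class = "c2_integrity_error")
  }
  left <- sort(unique(cls[pa$side == "left" & !cls %in% exclusion]))
  right <- sort(unique(cls[pa$side == "right" & !cls %in% exclusion]))
  new_signature(source_db, local_id, left, right)
}

new_signature <- function(source_db, local_id, left, right) {
  structure(list(key = rec_key(source_db, local_id),
                 source_db = source_db, local_id = local_id,
                 left = left, right = right,
                 size = length(left) + length(right)),
            class = "c2_signature")
}

#' @export
print.c2_signature <- function(x, ...) {
  cat("<signature ", x$key, "> {", paste(x$left, collapse = ", "), "} / {",
      paste(x$right, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# long table of all reaction signatures: (source_db, local_id, side, class_id),
# with a companion per-reaction size table; reactions whose signature is empty
# keep a row in sizes with size 0
corpus_signatures <- function(corpus,
                              met_classes = metabolite_classes(corpus),
                              exclusion = default_exclusion_classes(corpus)) {
  key <- paste(length(exclusion), paste(exclusion, collapse = "\r"), sep = "\r")
  cached(corpus, paste0("signatures\r", key), function() {
    cls_of <- setNames(met_classes$class_id,
                       rec_key(met_classes$source_db, met_classes$local_id))
    pa <- corpus$participants
    cls <- unname(cls_of[rec_key(pa$source_db, pa$metabolite_id)])
    if (anyNA(cls)) abort("unresolved participant metabolite(s)",
                          class = "c2_integrity_error")
    long <- tibble(source_db = pa$source_db, local_id = pa$reaction_id,
                   side = pa$side, class_id = cls) %>%
      filter(!.data$class_id %in% exclusion) %>%
      distinct()
    sizes <- corpus$reactions %>%
      select("source_db", "local_id") %>%
      left_join(count(long, .data$source_db, .data$local_id, name = "size"),
                by = c("source_db", "local_id")) %>%
      mutate(size = dplyr::coalesce(.data$size, 0L))
    list(long = long, sizes = sizes)
  })
}

signature_from_long <- function(long, sizes, i) {
  sd <- sizes$source_db[i]; id <- sizes$local_id[i]
  s <- long %>% filter(.data$source_db == sd, .data$local_id == id)
  new_signature(sd, id, sort(s$class_id[s$side == "left"]),
                sort(s$class_id[s$side == "right"]))
}

#' Percentage of overlap between two reactions
#'
#' The similarity of two reactions is the number of matching metabolites
#' divided by the metabolite count of the larger reaction, times 100 —
#' computed on signatures, i.e. respecting the two sides of a reaction but
#' ignoring its direction. Matching is evaluated in both orientations
#' (parallel: left-left + right-right; antiparallel: left-right +
#' right-left) and the better one is used, so reactions written in opposite
#' conventions still match. Two empty signatures overlap 0%, not 100%.
#'
#' @param s1,s2 `c2_signature` objects built with the same class mapping and
#'   exclusion set.
#' @return A `c2_overlap`: list with `percent` (rational, in \[0, 100\]),
#'   `matches`, `size1`, `size2`, `orientation` (`"parallel"` or
#'   `"antiparallel"`).
#' @export
overlap <- function(s1, s2) {
  stopifnot(inherits(s1, "c2_signature"), inherits(s2, "c2_signature"))
  par <- length(intersect(s1$left, s2$left)) + length(intersect(s1$right, s2$right))
  anti <- length(intersect(s1$left, s2$right)) + length(intersect(s1$right, s2$left))
  matches <- max(par, anti)
  denom <- max(s1$size, s2$size)
  percent <- if (denom == 0L) 0 else matches / denom * 100
  structure(list(percent = percent, matches = matches,
                 size1 = s1$size, size2 = s2$size,
                 orientation = if (par >= anti) "parallel" else "antiparallel"),
            class = "c2_overlap")
}

#' @export
print.c2_overlap <- function(x, ...) {
  cat("<overlap> ", display_percent(x$percent), "% (", x$matches, "/",
      max(x$size1, x$size2), ", ", x$orientation, ")\n", sep = "")
  invisible(x)
}

#' Integer display rendering of an overlap percentage
#'
#' Overlap percentages are displayed as whole numbers, truncated toward
#' zero (a 2-of-3 match displays as 66). Internal values stay rational.
#'
#' @param percent Numeric in \[0, 100\].
#' @return Integer vector.
#' @export
display_percent <- function(percent) {
  stopifnot(all(percent >= 0 & percent <= 100))
  as.integer(floor(percent + 1e-9))
}

#' Number of unmatched metabolites between two signatures
#'
#' `max(size1, size2) - matches` under the best orientation; 0 iff the
#' overlap is 100%. This is the quantity bounded by the mismatch budget of
#' a tolerant reaction query.
#'
#' @inheritParams overlap
#' @return Non-negative integer.
#' @export
mismatch_count <- function(s1, s2) {
  ov <- overlap(s1, s2)
  as.integer(max(ov$size1, ov$size2) - ov$matches)
}
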