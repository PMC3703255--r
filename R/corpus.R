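# ---- corpus container -------------------------------------------------------
#
# A corpus is a named list of tibbles, one per interchange table, each row
# carrying its source database label. Matching- and overlap-level derivations
# (equivalence classes, signatures) are computed lazily and memoised in an
# environment attribute; every constructor/modifier installs a fresh cache.

MET_ID_NAMESPACES <- c("kegg_compound", "kegg_glycan", "chebi",
                       "pubchem_compound", "pubchem_substance", "cas")
GENE_ID_NAMESPACES <- c("entrez", "ensembl", "uniprot")
ID_STATUSES <- c("current", "transferred", "obsolete")
DIRECTIONS <- c("forward", "reversible", "unknown")

corpus_schema <- function() {
  chr <- function(...) setNames(rep("c", length(c(...))), c(...))
  list(
    databases = chr("source_db", "version", "url_template"),
    metabolites = chr("source_db", "local_id", "primary_name", "synonyms",
                      "formula", MET_ID_NAMESPACES, "inchi", "smiles",
                      paste0(MET_ID_NAMESPACES, "_status")),
    genes = chr("source_db", "local_id", GENE_ID_NAMESPACES, "hgnc",
                paste0(GENE_ID_NAMESPACES, "_status")),
    reactions = chr("source_db", "local_id", "direction"),
    participants = c(chr("source_db", "reaction_id", "metabolite_id", "side",
                         "compartment"), stoichiometry = "d"),
    reaction_genes = chr("source_db", "reaction_id", "association_text", "dialect"),
    reaction_ec = chr("source_db", "reaction_id", "ec", "ec_status"),
    reaction_pathways = chr("source_db", "reaction_id", "pathway_id"),
    pathways = chr("source_db", "pathway_id", "name"),
    ec_reference = chr("ec", "enzyme_name", "reference_reaction")
  )
}

empty_table <- function(spec) {
  cols <- lapply(spec, function(t) if (t == "d") numeric() else character())
  tibble::as_tibble(cols)
}

conform_table <- function(tbl, spec, name) {
  if (is.null(tbl)) return(empty_table(spec))
  tbl <- as_tibble(tbl)
  for (col in names(spec)) {
    if (!col %in% names(tbl)) {
      tbl[[col]] <- if (spec[[col]] == "d") NA_real_ else NA_character_
    }
  }
  extra <- setdiff(names(tbl), names(spec))
  if (length(extra)) {
    abort(paste0("unknown column(s) in ", name, ": ", paste(extra, collapse = ", ")),
          class = "c2_schema_error")
  }
  tbl <- tbl[names(spec)]
  for (col in names(spec)) {
    tbl[[col]] <- if (spec[[col]] == "d") as.numeric(tbl[[col]]) else {
      v <- as.character(tbl[[col]])
      v[!is.na(v) & !nzchar(v)] <- NA_character_
      v
    }
  }
  # absent status = current
  st <- grep("_status$", names(spec), value = TRUE)
  for (col in st) tbl[[col]] <- dplyr::coalesce(tbl[[col]], "current")
  tbl
}

#' Construct a corpus of pathway-database descriptions
#'
#' A corpus bundles one or more independently curated descriptions of the
#' same organism's metabolic network. Each table is a tibble with a
#' `source_db` column; missing columns are filled with `NA` and identifier
#' status columns default to `"current"`.
#'
#' @param databases,metabolites,genes,reactions,participants,reaction_genes,
#'   reaction_ec,reaction_pathways,pathways,ec_reference Data frames in the
#'   interchange schema (any may be omitted).
#' @param validate Run [validate_corpus()] on the result (default `TRUE`).
#' @return A `c2_corpus` object (a named list of tibbles).
#' @export
c2_corpus <- function(databases = NULL, metabolites = NULL, genes = NULL,
                      reactions = NULL, participants = NULL,
                      reaction_genes = NULL, reaction_ec = NULL,
                      reaction_pathways = NULL, pathways = NULL,
                      ec_reference = NULL, validate = TRUE) {
  schema <- corpus_schema()
  tables <- list(databases = databases, metabolites = metabolites,
                 genes = genes, reactions = reactions,
                 participants = participants, reaction_genes = reaction_genes,
                 reaction_ec = reaction_ec, reaction_pathways = reaction_pathways,
                 pathways = pathways, ec_reference = ec_reference)
  corpus <- purrr::imap(tables, function(tbl, nm) conform_table(tbl, schema[[nm]], nm))
  # databases may be implicit in the record tables
  seen <- unique(unlist(lapply(corpus[setdiff(names(corpus), c("databases", "ec_reference"))],
                               function(t) t$source_db)))
  seen <- seen[!is.na(seen)]
  missing_db <- setdiff(seen, corpus$databases$source_db)
  if (length(missing_db)) {
    corpus$databases <- bind_rows(corpus$databases,
                                  tibble(source_db = missing_db,
                                         version = NA_character_,
                                         url_template = NA_character_))
  }
  corpus <- structure(corpus, class = "c2_corpus")
  corpus <- corpus_sort(corpus)
  attr(corpus, "cache") <- new.env(parent = emptyenv())
  if (validate) validate_corpus(corpus)
  corpus
}

# canonical record ordering so exports are byte-stable
corpus_sort <- function(corpus) {
  ord <- list(
    databases = "source_db",
    metabolites = c("source_db", "local_id"),
    genes = c("source_db", "local_id"),
    reactions = c("source_db", "local_id"),
    participants = c("source_db", "reaction_id", "side", "metabolite_id", "compartment"),
    reaction_genes = c("source_db", "reaction_id"),
    reaction_ec = c("source_db", "reaction_id", "ec"),
    reaction_pathways = c("source_db", "reaction_id", "pathway_id"),
    pathways = c("source_db", "pathway_id"),
    ec_reference = "ec"
  )
  for (nm in names(ord)) {
    corpus[[nm]] <- dplyr::arrange(corpus[[nm]], across(all_of(ord[[nm]])))
  }
  corpus
}

# rebuild class + fresh cache after any modification
corpus_rebuild <- function(corpus, validate = FALSE) {
  do.call(c2_corpus, c(unclass(corpus)[names(corpus_schema())], list(validate = validate)))
}

#' Validate a corpus
#'
#' Enforces referential integrity and field invariants: unique local ids per
#' source database, participants resolving to known metabolites and
#' reactions, at least one participant on each side of every reaction, legal
#' direction/side/status values, parseable EC numbers and gene associations
#' whose leaves are known genes.
#'
#' @param corpus A `c2_corpus`.
#' @return The corpus, invisibly; aborts with a `c2_validation_error` listing
#'   every offender otherwise.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "c2_corpus"))
  problems <- corpus_problems(corpus)
  if (nrow(problems)) {
    msg <- paste0("corpus validation failed (", nrow(problems), " problem(s)):\n",
                  paste0("  - [", problems$table, "] ", problems$problem,
                         collapse = "\n"))
    abort(msg, class = "c2_validation_error", problems = problems)
  }
  invisible(corpus)
}

# returns a tibble (table, problem, row) of every violation; row indexes the
# canonical-order tibble and lets read_corpus() map back to file lines
corpus_problems <- function(corpus) {
  probs <- list()
  note <- function(table, rows, what) {
    if (length(rows)) {
      probs[[length(probs) + 1L]] <<- tibble(table = table, row = as.integer(rows),
                                             problem = what)
    }
  }
  dbs <- corpus$databases$source_db
  note("databases", which(duplicated(dbs)), "duplicate source_db")
  for (nm in setdiff(names(corpus_schema()), c("databases", "ec_reference"))) {
    bad <- which(!corpus[[nm]]$source_db %in% dbs | is.na(corpus[[nm]]$source_db))
    note(nm, bad, "unknown or missing source_db")
  }
  for (nm in c("metabolites", "genes", "reactions")) {
    key <- paste(corpus[[nm]]$source_db, corpus[[nm]]$local_id)
    note(nm, which(is.na(corpus[[nm]]$local_id)), "missing local_id")
    note(nm, which(duplicated(key)), "duplicate local_id within source_db")
  }
  note("pathways", which(duplicated(paste(corpus$pathways$source_db,
                                          corpus$pathways$pathway_id))),
       "duplicate pathway_id within source_db")

  met_keys <- paste(corpus$metabolites$source_db, corpus$metabolites$local_id)
  rxn_keys <- paste(corpus$reactions$source_db, corpus$reactions$local_id)
  pw_keys <- paste(corpus$pathways$source_db, corpus$pathways$pathway_id)
  gene_keys <- paste(corpus$genes$source_db, corpus$genes$local_id)

  pa <- corpus$participants
  note("participants", which(!paste(pa$source_db, pa$metabolite_id) %in% met_keys),
       "participant references unknown metabolite")
  note("participants", which(!paste(pa$source_db, pa$reaction_id) %in% rxn_keys),
       "participant references unknown reaction")
  note("participants", which(!pa$side %in% c("left", "right")),
       "side must be 'left' or 'right'")
  note("participants", which(!is.na(pa$stoichiometry) & pa$stoichiometry <= 0),
       "stoichiometry must be positive")

  note("reactions", which(!corpus$reactions$direction %in% DIRECTIONS),
       paste0("direction must be one of ", paste(DIRECTIONS, collapse = "/")))
  # each side populated
  ok <- pa %>% filter(.data$side %in% c("left", "right")) %>%
    distinct(.data$source_db, .data$reaction_id, .data$side) %>%
    count(.data$source_db, .data$reaction_id)
  two_sided <- paste(ok$source_db[ok$n == 2L], ok$reaction_id[ok$n == 2L])
  note("reactions", which(!rxn_keys %in% two_sided),
       "reaction must have at least one participant on each side")

  rg <- corpus$reaction_genes
  note("reaction_genes", which(!paste(rg$source_db, rg$reaction_id) %in% rxn_keys),
       "gene association references unknown reaction")
  note("reaction_genes", which(!rg$dialect %in% c("boolean", "list")),
       "dialect must be 'boolean' or 'list'")
  if (nrow(rg)) {
    for (i in seq_len(nrow(rg))) {
      if (!rg$dialect[i] %in% c("boolean", "list")) next
      leaves <- tryCatch(
        assoc_leaves(parse_gene_association(rg$association_text[i], rg$dialect[i])),
        error = function(e) {
          note("reaction_genes", i, paste0("unparseable association: ",
                                           conditionMessage(e)))
          character()
        })
      miss <- leaves[!paste(rg$source_db[i], leaves) %in% gene_keys]
      note("reaction_genes", rep(i, length(miss)),
           paste0("association references unknown gene '", miss, "'"))
    }
  }

  re <- corpus$reaction_ec
  note("reaction_ec", which(!paste(re$source_db, re$reaction_id) %in% rxn_keys),
       "EC link references unknown reaction")
  bad_ec <- which(vapply(re$ec, function(e) {
    is.na(e) || inherits(tryCatch(ec_parse(e), error = identity), "error")
  }, logical(1)))
  note("reaction_ec", bad_ec, "malformed EC number")
  note("reaction_ec", which(!re$ec_status %in% ID_STATUSES), "bad ec_status")

  rp <- corpus$reaction_pathways
  note("reaction_pathways", which(!paste(rp$source_db, rp$reaction_id) %in% rxn_keys),
       "pathway link references unknown reaction")
  note("reaction_pathways", which(!paste(rp$source_db, rp$pathway_id) %in% pw_keys),
       "pathway link references unknown pathway")

  for (nm in c("metabolites", "genes")) {
    st_cols <- grep("_status$", names(corpus[[nm]]), value = TRUE)
    for (col in st_cols) {
      note(nm, which(!corpus[[nm]][[col]] %in% ID_STATUSES),
           paste0(col, " must be one of ", paste(ID_STATUSES, collapse = "/")))
    }
  }
  if (length(probs)) dplyr::arrange(bind_rows(probs), .data$table, .data$row)
  else tibble(table = character(), row = integer(), problem = character())
}

#' @export
print.c2_corpus <- function(x, ...) {
  cat("<c2_corpus> ", nrow(x$databases), " database(s): ",
      paste(x$databases$source_db, collapse = ", "), "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      " | genes: ", nrow(x$genes),
      " | reactions: ", nrow(x$reactions),
      " | pathways: ", nrow(x$pathways), "\n", sep = "")
  invisible(x)
}

# ---- lazy derivation cache --------------------------------------------------

corpus_cache <- function(corpus) {
  cache <- attr(corpus, "cache")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  cache
}

cached <- function(corpus, key, builder) {
  cache <- corpus_cache(corpus)
  if (!exists(key, envir = cache, inherits = FALSE)) {
    assign(key, builder(), envir = cache)
  }
  get(key, envir = cache, inherits = FALSE)
}

rec_key <- function(source_db, local_id) paste(source_db, local_id, sep = ":")
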