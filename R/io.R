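# ---- interchange format -----------------------------------------------------
#
# One subdirectory per source database holding the TSV tables below; all
# UTF-8 with a mandatory header row, empty string = absent value. Identifier
# status columns (<namespace>_status) are optional on read (absent = current)
# and always written so exports are byte-stable.

INTERCHANGE_FILES <- c("metabolites", "genes", "reactions", "participants",
                       "reaction_genes", "reaction_ec", "reaction_pathways",
                       "pathways")

# per-file on-disk column sets (status columns included; source_db implicit)
interchange_cols <- function(table) {
  spec <- corpus_schema()[[table]]
  setdiff(names(spec), "source_db")
}

#' Read a corpus from an interchange directory
#'
#' Expects one subdirectory per source database containing `metabolites.tsv`,
#' `genes.tsv`, `reactions.tsv`, `participants.tsv`, `reaction_genes.tsv`,
#' `reaction_ec.tsv`, `reaction_pathways.tsv` and `pathways.tsv` (all
#' mandatory, header row required), plus an optional `database.tsv`
#' (version, url_template). An optional root-level `ec_reference.tsv`
#' supplies per-EC reference reaction/name text.
#'
#' @param root_directory Path to the corpus root.
#' @return A validated `c2_corpus`. Malformed rows are reported with file and
#'   line; dangling references abort with a `c2_validation_error` listing the
#'   offenders.
#' @export
read_corpus <- function(root_directory) {
  if (!dir.exists(root_directory)) {
    abort(paste0("corpus directory not found: ", root_directory),
          class = "c2_load_error")
  }
  db_dirs <- sort(list.dirs(root_directory, recursive = FALSE))
  tables <- setNames(vector("list", length(INTERCHANGE_FILES)), INTERCHANGE_FILES)
  databases <- list()
  for (d in db_dirs) {
    db <- basename(d)
    for (tb in INTERCHANGE_FILES) {
      path <- file.path(d, paste0(tb, ".tsv"))
      if (!file.exists(path)) {
        abort(paste0("missing mandatory table: ", path), class = "c2_load_error")
      }
      tbl <- read_interchange_tsv(path, tb)
      tbl$source_db <- rep(db, nrow(tbl))
      tables[[tb]] <- c(tables[[tb]], list(tbl))
    }
    meta_path <- file.path(d, "database.tsv")
    meta <- tibble(source_db = db, version = NA_character_,
                   url_template = NA_character_)
    if (file.exists(meta_path)) {
      m <- readr::read_tsv(meta_path, col_types = readr::cols(.default = "c"),
                           na = "", progress = FALSE)
      if (nrow(m)) {
        if ("version" %in% names(m)) meta$version <- m$version[1]
        if ("url_template" %in% names(m)) meta$url_template <- m$url_template[1]
      }
    }
    databases <- c(databases, list(meta))
  }
  ec_ref <- NULL
  ec_ref_path <- file.path(root_directory, "ec_reference.tsv")
  if (file.exists(ec_ref_path)) {
    ec_ref <- readr::read_tsv(ec_ref_path, col_types = readr::cols(.default = "c"),
                              na = "", progress = FALSE)
  }
  corpus <- withCallingHandlers(
    c2_corpus(
      databases = if (length(databases)) bind_rows(databases) else NULL,
      metabolites = bind_rows(tables$metabolites),
      genes = bind_rows(tables$genes),
      reactions = bind_rows(tables$reactions),
      participants = bind_rows(tables$participants),
      reaction_genes = bind_rows(tables$reaction_genes),
      reaction_ec = bind_rows(tables$reaction_ec),
      reaction_pathways = bind_rows(tables$reaction_pathways),
      pathways = bind_rows(tables$pathways),
      ec_reference = ec_ref,
      validate = FALSE
    ),
    error = function(e) e)
  problems <- corpus_problems(corpus)
  if (nrow(problems)) {
    # map canonical-order rows back to file + line (header = line 1)
    locate <- function(table, row) {
      tbl <- corpus[[table]]
      db <- tbl$source_db[row]
      paste0(file.path(root_directory, db, paste0(table, ".tsv")),
             " (record ", row, " of ", table, " for ", db, ")")
    }
    msg <- paste0("invalid corpus at ", root_directory, ":\n",
                  paste0("  - ", purrr::map2_chr(problems$table, problems$row,
                                                 locate),
                         ": ", problems$problem, collapse = "\n"))
    abort(msg, class = "c2_validation_error", problems = problems)
  }
  corpus
}

read_interchange_tsv <- function(path, table) {
  schema <- corpus_schema()[[table]]
  hdr <- readr::read_tsv(path, n_max = 0, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  known <- interchange_cols(table)
  extra <- setdiff(names(hdr), known)
  if (length(extra)) {
    abort(paste0(path, ": unknown column(s): ", paste(extra, collapse = ", ")),
          class = "c2_load_error")
  }
  types <- vapply(names(hdr), function(col) {
    if (identical(schema[[col]], "d")) "d" else "c"
  }, character(1))
  tbl <- readr::read_tsv(path, col_types = paste(types, collapse = ""),
                         na = "", progress = FALSE, show_col_types = FALSE)
  pr <- readr::problems(tbl)
  if (nrow(pr)) {
    abort(paste0(path, ": malformed row(s) at line(s) ",
                 paste(unique(pr$row + 1L), collapse = ", ")),
          class = "c2_load_error")
  }
  tbl
}

#' Write a corpus to an interchange directory
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(c, d))` is
#' record-identical to `c`. Records are written in the canonical
#' `(source_db, local_id)` sort order so repeated exports are byte-stable.
#'
#' @param corpus A `c2_corpus`.
#' @param root_directory Target directory (created if needed).
#' @return `root_directory`, invisibly.
#' @export
write_corpus <- function(corpus, root_directory) {
  stopifnot(inherits(corpus, "c2_corpus"))
  corpus <- corpus_sort(corpus)
  dir.create(root_directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root_directory)) {
    abort(paste0("cannot create directory: ", root_directory), class = "c2_io_error")
  }
  for (db in corpus$databases$source_db) {
    d <- file.path(root_directory, db)
    dir.create(d, showWarnings = FALSE)
    for (tb in INTERCHANGE_FILES) {
      tbl <- corpus[[tb]] %>% filter(.data$source_db == db) %>%
        select(all_of(interchange_cols(tb)))
      readr::write_tsv(tbl, file.path(d, paste0(tb, ".tsv")), na = "",
                       progress = FALSE)
    }
    meta <- corpus$databases %>% filter(.data$source_db == db) %>%
      select("version", "url_template")
    readr::write_tsv(meta, file.path(d, "database.tsv"), na = "", progress = FALSE)
  }
  if (nrow(corpus$ec_reference)) {
    readr::write_tsv(corpus$ec_reference, file.path(root_directory, "ec_reference.tsv"),
                     na = "", progress = FALSE)
  }
  invisible(root_directory)
}

# ---- identifier updates -----------------------------------------------------

#' Read an identifier-update table
#'
#' Tab-separated with columns `kind` (`gene_id`, `metabolite_id` or
#' `ec_number`), `old`, and `new` (the replacement value, or the literal
#' `OBSOLETE`). Tables must be pre-flattened: an update chain (a -> b and
#' b -> c) is an input error.
#'
#' @param path TSV file path.
#' @return A tibble (kind, old, new).
#' @export
read_id_updates <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "ccc", na = "", progress = FALSE,
                         show_col_types = FALSE)
  if (!all(c("kind", "old", "new") %in% names(tbl))) {
    abort(paste0(path, ": id update table needs columns kind, old, new"),
          class = "c2_load_error")
  }
  check_id_updates(tbl)
  tbl
}

check_id_updates <- function(tables) {
  bad_kind <- setdiff(unique(tables$kind), c("gene_id", "metabolite_id", "ec_number"))
  if (length(bad_kind)) {
    abort(paste0("unknown id-update kind: ", paste(bad_kind, collapse = ", ")),
          class = "c2_config_error")
  }
  chained <- tables %>%
    filter(.data$new != "OBSOLETE") %>%
    semi_join(tables, by = c("kind", "new" = "old"))
  if (nrow(chained)) {
    abort(paste0("id-update table contains chains (must be pre-flattened): ",
                 paste(chained$old, "->", chained$new, collapse = ", ")),
          class = "c2_config_error")
  }
  dup <- tables$old[duplicated(paste(tables$kind, tables$old))]
  if (length(dup)) {
    abort(paste0("duplicate update entries for: ", paste(dup, collapse = ", ")),
          class = "c2_config_error")
  }
  invisible(tables)
}

#' Apply identifier-update tables to a corpus
#'
#' Out-of-date identifiers and EC numbers are transferred to their current
#' value and flagged `transferred`; entries mapping to `OBSOLETE` keep the
#' old value flagged `obsolete`. Obsolete identifiers are subsequently
#' excluded from all matching. Idempotent: applying the same tables twice
#' equals applying once.
#'
#' @param corpus A `c2_corpus`.
#' @param tables A tibble (kind, old, new) as from [read_id_updates()];
#'   kind is one of `gene_id`, `metabolite_id`, `ec_number`.
#' @return The updated corpus.
#' @export
apply_id_updates <- function(corpus, tables) {
  stopifnot(inherits(corpus, "c2_corpus"))
  if (is.null(tables) || nrow(tables) == 0L) return(corpus)
  check_id_updates(tables)

  upd_one <- function(values, statuses, kind) {
    tab <- tables[tables$kind == kind, ]
    if (!nrow(tab)) return(list(values = values, statuses = statuses))
    i <- match(values, tab$old)
    hit <- !is.na(i) & !is.na(values)
    obsolete <- hit & tab$new[i] == "OBSOLETE"
    transfer <- hit & !obsolete
    values[transfer] <- tab$new[i[transfer]]
    statuses[transfer] <- "transferred"
    statuses[obsolete] <- "obsolete"
    list(values = values, statuses = statuses)
  }

  for (ns in GENE_ID_NAMESPACES) {
    r <- upd_one(corpus$genes[[ns]], corpus$genes[[paste0(ns, "_status")]], "gene_id")
    corpus$genes[[ns]] <- r$values
    corpus$genes[[paste0(ns, "_status")]] <- r$statuses
  }
  for (ns in MET_ID_NAMESPACES) {
    r <- upd_one(corpus$metabolites[[ns]],
                 corpus$metabolites[[paste0(ns, "_status")]], "metabolite_id")
    corpus$metabolites[[ns]] <- r$values
    corpus$metabolites[[paste0(ns, "_status")]] <- r$statuses
  }
  r <- upd_one(corpus$reaction_ec$ec, corpus$reaction_ec$ec_status, "ec_number")
  corpus$reaction_ec$ec <- r$values
  corpus$reaction_ec$ec_status <- r$statuses
  corpus_rebuild(corpus)
}

#' Convert PubChem Substance ids to Compound ids
#'
#' Substance ids are depositor-specific; Compound ids unite them. Records
#' whose `pubchem_substance` id has a mapping gain the corresponding
#' `pubchem_compound` id (existing compound ids are never overwritten).
#' Unmapped substance ids are retained for display but are never used for
#' matching.
#'
#' @param corpus A `c2_corpus`.
#' @param cid_sid_map A tibble with columns `substance_id`, `compound_id`.
#' @return The updated corpus.
#' @export
convert_substance_ids <- function(corpus, cid_sid_map) {
  stopifnot(inherits(corpus, "c2_corpus"))
  if (is.null(cid_sid_map) || nrow(cid_sid_map) == 0L) return(corpus)
  if (!all(c("substance_id", "compound_id") %in% names(cid_sid_map))) {
    abort("cid_sid_map needs columns substance_id, compound_id",
          class = "c2_config_error")
  }
  i <- match(corpus$metabolites$pubchem_substance, cid_sid_map$substance_id)
  gain <- !is.na(i) & is.na(corpus$metabolites$pubchem_compound) &
    corpus$metabolites$pubchem_substance_status != "obsolete"
  corpus$metabolites$pubchem_compound[gain] <-
    as.character(cid_sid_map$compound_id[i[gain]])
  corpus_rebuild(corpus)
}
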