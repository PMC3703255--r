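# ---- card serialization -----------------------------------------------------

CARD_TSV_HEADER <- c("Database", "Reaction", "Overlap(%)", "EC number",
                     "Gene(s)", "Pathway")

#' Render a card for off-line use
#'
#' TSV emits the core table with the fixed column order Database, Reaction,
#' Overlap(%), EC number, Gene(s), Pathway (Overlap(%) is filled on the
#' reaction perspective and empty otherwise). JSON mirrors the full card
#' model, including the similarity table and the identifier panels, and
#' reserves an `extensions` field for downstream annotation systems.
#'
#' @param card A `c2_card`.
#' @param format `"tsv"` or `"json"`.
#' @return A single string (deterministic serialization).
#' @export
render_card <- function(card, format = c("tsv", "json")) {
  stopifnot(inherits(card, "c2_card"))
  format <- match.arg(format)
  if (format == "tsv") {
    rows <- card$rows
    body <- if (nrow(rows) == 0L) character() else {
      apply(cbind(rows$source_db, rows$reaction,
                  ifelse(is.na(rows$overlap), "", rows$overlap),
                  rows$ec, rows$genes, rows$pathway),
            1, paste, collapse = "\t")
    }
    paste0(paste(c(paste(CARD_TSV_HEADER, collapse = "\t"), body),
                 collapse = "\n"), "\n")
  } else {
    payload <- list(
      schema_version = "1.0",
      focus = card$focus,
      rows = card$rows,
      similarity = card$similarity,
      id_panels = card$id_panels,
      ec_panels = card$ec_panels,
      extensions = list()
    )
    jsonlite::toJSON(payload, dataframe = "rows", na = "null",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
}

#' Parse a JSON-rendered card back into a `c2_card`
#'
#' @param json JSON text from `render_card(card, "json")`.
#' @return A `c2_card`; `render_card(parse_card(x), "json")` is stable.
#' @export
parse_card <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  fix <- function(df, template) {
    df <- as_tibble(if (is.null(df) || length(df) == 0L) template[0, ] else df)
    for (col in names(template)) {
      if (!col %in% names(df)) df[[col]] <- template[[col]][0][NA]
    }
    df[names(template)]
  }
  new_card(p$focus$kind, p$focus$key,
           fix(p$rows, empty_card_rows()),
           as_tibble(if (is.null(p$similarity)) data.frame() else p$similarity),
           list(metabolites = as_tibble(p$id_panels$metabolites),
                genes = as_tibble(p$id_panels$genes)),
           as_tibble(if (is.null(p$ec_panels)) data.frame() else p$ec_panels))
}

#' Similarity banding for presentation
#'
#' Maps display percentages onto coarse agreement bands (a presentation
#' concern; defaults: exact = 100, high >= 50, partial > 0, none = 0).
#'
#' @param percent_display Integer display percentages.
#' @param breaks Named thresholds `c(exact = , high = )`.
#' @return Factor with levels exact/high/partial/none.
#' @export
overlap_band <- function(percent_display, breaks = c(exact = 100, high = 50)) {
  factor(ifelse(percent_display >= breaks[["exact"]], "exact",
         ifelse(percent_display >= breaks[["high"]], "high",
         ifelse(percent_display > 0, "partial", "none"))),
         levels = c("exact", "high", "partial", "none"))
}

#' Export every card of a corpus
#'
#' Writes, for each source database and each perspective (gene, EC number,
#' reaction), one card file per entity, plus an `index.tsv` per export set
#' mapping entity to file. Layout:
#' `out_dir/<database>/<perspective>/<entity>.tsv`.
#'
#' @param corpus A `c2_corpus`.
#' @param out_dir Target directory.
#' @param format `"tsv"` or `"json"`.
#' @return A tibble (source_db, perspective, entity, file), invisibly; the
#'   same content is written to the index files.
#' @export
export_all <- function(corpus, out_dir, format = "tsv") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create directory: ", out_dir), class = "c2_io_error")
  }
  exclusion <- default_exclusion_classes(corpus)
  gcls <- gene_classes(corpus)
  ext <- if (format == "tsv") ".tsv" else ".json"
  slug <- function(x) gsub("[^[:alnum:]._-]", "_", x)
  index <- list()
  for (db in corpus$databases$source_db) {
    # gene perspective: one card per gene class present in this database
    per <- list(
      gene = gcls %>% filter(.data$source_db == db) %>% pull("class_id") %>%
        unique(),
      ec = corpus$reaction_ec %>% filter(.data$source_db == db) %>%
        pull("ec") %>% unique() %>% sort(),
      reaction = corpus$reactions %>% filter(.data$source_db == db) %>%
        pull("local_id")
    )
    for (persp in names(per)) {
      d <- file.path(out_dir, db, persp)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      entries <- purrr::map_dfr(per[[persp]], function(entity) {
        card <- switch(persp,
          gene = gene_card(corpus, entity, exclusion = exclusion),
          ec = ec_card(corpus, entity, exclusion = exclusion),
          reaction = reaction_card(corpus, rec_key(db, entity),
                                   exclusion = exclusion))
        file <- file.path(d, paste0(slug(entity), ext))
        writeLines(render_card(card, format), file, useBytes = TRUE)
        tibble(source_db = db, perspective = persp, entity = entity,
               file = file)
      })
      if (nrow(entries)) {
        readr::write_tsv(entries, file.path(d, "index.tsv"), na = "",
                         progress = FALSE)
        index <- c(index, list(entries))
      }
    }
  }
  invisible(if (length(index)) bind_rows(index) else
            tibble(source_db = character(), perspective = character(),
                   entity = character(), file = character()))
}
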