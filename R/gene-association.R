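#' Parse a gene association expression
#'
#' Reactions are linked to genes by a Boolean expression: `or` joins isozymes
#' (independent catalysts), parenthesized `and` groups join subunits of a
#' complex. Some source databases have no syntax for either concept and just
#' list genes; the `list` dialect captures that with explicit
#' unknown-semantics (`LIST`) nodes, rendered comma-separated.
#'
#' @param text Association text. Boolean dialect grammar: leaves, `or`,
#'   parenthesized `and` groups, e.g. `"(A and B) or C"`. List dialect:
#'   comma-separated leaves, e.g. `"A, B"`.
#' @param dialect `"boolean"` or `"list"`.
#' @return A `c2_gene_assoc` tree: either a leaf (character scalar) or
#'   `list(op = "AND"|"OR"|"LIST", args = <children>)`.
#' @examples
#' parse_gene_association("(A and B) or C")
#' parse_gene_association("A, B", dialect = "list")
#' @export
parse_gene_association <- function(text, dialect = c("boolean", "list")) {
  dialect <- match.arg(dialect)
  text <- stringr::str_trim(text)
  if (!nzchar(text)) abort("empty gene association text", class = "c2_parse_error")
  tree <- if (dialect == "list") {
    leaves <- stringr::str_trim(strsplit(text, ",", fixed = TRUE)[[1]])
    leaves <- leaves[nzchar(leaves)]
    if (length(leaves) == 0L) abort("empty gene list", class = "c2_parse_error")
    if (length(leaves) == 1L) leaves else list(op = "LIST", args = as.list(leaves))
  } else {
    toks <- assoc_tokenize(text)
    st <- assoc_parse_or(toks, 1L)
    if (st$pos <= length(toks)) {
      abort(paste0("trailing tokens in gene association: '", text, "'"),
            class = "c2_parse_error")
    }
    st$node
  }
  structure(list(tree = tree, dialect = dialect), class = "c2_gene_assoc")
}

assoc_tokenize <- function(text) {
  m <- stringr::str_match_all(text, "\\(|\\)|[^()\\s]+")[[1]][, 1]
  if (paste(gsub("\\s", "", m), collapse = "") != gsub("\\s", "", text)) {
    abort("unlexable gene association", class = "c2_parse_error")
  }
  m
}

# expr := term ("or" term)*
assoc_parse_or <- function(toks, pos) {
  st <- assoc_parse_and(toks, pos)
  args <- list(st$node); pos <- st$pos
  while (pos <= length(toks) && tolower(toks[pos]) == "or") {
    st <- assoc_parse_and(toks, pos + 1L)
    args <- c(args, list(st$node)); pos <- st$pos
  }
  node <- if (length(args) == 1L) args[[1]] else list(op = "OR", args = args)
  list(node = node, pos = pos)
}

# term := factor ("and" factor)*
assoc_parse_and <- function(toks, pos) {
  st <- assoc_parse_factor(toks, pos)
  args <- list(st$node); pos <- st$pos
  while (pos <= length(toks) && tolower(toks[pos]) == "and") {
    st <- assoc_parse_factor(toks, pos + 1L)
    args <- c(args, list(st$node)); pos <- st$pos
  }
  node <- if (length(args) == 1L) args[[1]] else list(op = "AND", args = args)
  list(node = node, pos = pos)
}

assoc_parse_factor <- function(toks, pos) {
  if (pos > length(toks)) abort("unexpected end of gene association", class = "c2_parse_error")
  tok <- toks[pos]
  if (tok == "(") {
    st <- assoc_parse_or(toks, pos + 1L)
    if (st$pos > length(toks) || toks[st$pos] != ")") {
      abort("unbalanced parentheses in gene association", class = "c2_parse_error")
    }
    list(node = st$node, pos = st$pos + 1L)
  } else if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    abort(paste0("unexpected token '", tok, "' in gene association"),
          class = "c2_parse_error")
  } else {
    list(node = tok, pos = pos + 1L)
  }
}

#' Render a gene association to its canonical text
#'
#' `or` joins alternatives, `and` groups are parenthesized, `LIST` nodes
#' render comma-separated. Leaves can be mapped through a display function
#' (e.g. local gene ids to HGNC symbols).
#'
#' @param assoc A `c2_gene_assoc` from [parse_gene_association()].
#' @param display Function mapping a leaf string to its display text.
#' @return A single string.
#' @export
render_gene_association <- function(assoc, display = identity) {
  stopifnot(inherits(assoc, "c2_gene_assoc"))
  assoc_render_node(assoc$tree, display)
}

assoc_render_node <- function(node, display) {
  if (is.character(node)) return(display(node))
  parts <- vapply(node$args, assoc_render_node, character(1), display = display)
  switch(node$op,
    LIST = paste(parts, collapse = ", "),
    OR   = paste(parts, collapse = " or "),
    AND  = paste0("(", paste(parts, collapse = " and "), ")"),
    abort(paste0("unknown association operator: ", node$op))
  )
}

#' @export
print.c2_gene_assoc <- function(x, ...) {
  cat("<gene association [", x$dialect, "]> ", render_gene_association(x), "\n", sep = "")
  invisible(x)
}

# all gene leaves (local ids) of an association, deduplicated
assoc_leaves <- function(assoc) {
  rec <- function(node) {
    if (is.character(node)) node else unlist(lapply(node$args, rec))
  }
  unique(rec(assoc$tree))
}

#' Display symbol for gene records
#'
#' Genes are displayed by their HGNC symbol; multiple symbols are joined by
#' two underscores. When no symbol is known the Entrez id is shown, else the
#' Ensembl id, else the database-internal id. Total: every record renders to
#' a non-empty symbol.
#'
#' @param genes A genes tibble (columns `local_id`, `entrez`, `ensembl`,
#'   `hgnc`, with `hgnc` `|`-separated).
#' @return Character vector of display symbols, one per row.
#' @export
gene_display_symbol <- function(genes) {
  hg <- ifelse(is.na(genes$hgnc) | !nzchar(genes$hgnc), NA_character_,
               gsub("|", "__", genes$hgnc, fixed = TRUE))
  dplyr::coalesce(hg, genes$entrez, genes$ensembl, genes$local_id)
}
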