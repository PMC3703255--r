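#' Normalize a gene or metabolite name for matching
#'
#' Name matching is case-insensitive and ignores spaces and punctuation:
#' the text is lower-cased and every non-alphanumeric character is removed.
#' The function is total and idempotent.
#'
#' @param name Character vector.
#' @return Character vector of normalized keys (possibly empty strings).
#' @examples
#' normalize_name("L-Arginine")               # "larginine"
#' normalize_name("2-Deoxy-D-ribose 1-phosphate")
#' @export
normalize_name <- function(name) {
  gsub("[^[:alnum:]]", "", tolower(as.character(name)))
}

#' Parse a chemical formula into element counts
#'
#' Accepts Hill-style formulas of element symbols (`[A-Z][a-z]?`) with
#' optional integer counts; a trailing charge token (a sign optionally
#' followed by digits, e.g. `"CHO2-"`, `"C6H15NO2+2"`) is stripped before
#' parsing. Anything outside that grammar — polymer notation like
#' `"(C5H8)n"`, residue markers like `"R"` alone in context of groups,
#' parentheses — is unparseable and is reported as `NULL`; unparseable
#' formulas never satisfy a formula match.
#'
#' @param text A single formula string (or `NA`).
#' @return A named integer vector of element counts, or `NULL` if the text
#'   is missing or not in the grammar.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("CHO2-")
#' @export
parse_formula <- function(text) {
  if (length(text) != 1L) abort("parse_formula() is scalar; use lapply for vectors")
  if (is.na(text) || !nzchar(text)) return(NULL)
  s <- gsub("[+-][0-9]*$", "", stringr::str_trim(text))
  if (!nzchar(s)) return(NULL)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s)) return(NULL)
  m <- stringr::str_match_all(s, "([A-Z][a-z]?)([0-9]*)")[[1]]
  counts <- ifelse(m[, 3] == "", 1L, suppressWarnings(as.integer(m[, 3])))
  if (anyNA(counts) || any(counts < 1L)) return(NULL)
  out <- tapply(counts, m[, 2], sum)
  setNames(as.integer(out), names(out))
}

#' Compare two chemical formulas ignoring hydrogen
#'
#' Databases state reactions at different pH levels, so protonation shifts
#' the hydrogen count of otherwise identical species. Two formulas match iff
#' their element counts are equal for every element except H. Either side
#' unparseable means no match.
#'
#' @param f1,f2 Element-count vectors from [parse_formula()], or raw formula
#'   strings (parsed on the fly).
#' @return `TRUE` or `FALSE`.
#' @examples
#' formulas_match("C6H12O6", "C6H13O6")  # TRUE: H ignored
#' formulas_match("C6H12O6", "C5H12O6")  # FALSE
#' @export
formulas_match <- function(f1, f2) {
  if (is.character(f1)) f1 <- parse_formula(f1)
  if (is.character(f2)) f2 <- parse_formula(f2)
  if (is.null(f1) || is.null(f2)) return(FALSE)
  f1 <- f1[names(f1) != "H"]
  f2 <- f2[names(f2) != "H"]
  if (length(f1) != length(f2)) return(FALSE)
  f1 <- f1[order(names(f1))]
  f2 <- f2[order(names(f2))]
  identical(names(f1), names(f2)) && all(f1 == f2)
}

# vectorized H-insensitive comparison on formula *strings*; NA-safe.
# Used by the join-based metabolite class builder.
formulas_match_chr <- function(x, y) {
  key <- function(v) {
    vapply(v, function(t) {
      p <- parse_formula(if (is.na(t)) NA_character_ else t)
      if (is.null(p)) return(NA_character_)
      p <- p[names(p) != "H"]
      p <- p[order(names(p))]
      paste(names(p), p, sep = ":", collapse = ",")
    }, character(1), USE.NAMES = FALSE)
  }
  kx <- key(x); ky <- key(y)
  !is.na(kx) & !is.na(ky) & kx == ky
}
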