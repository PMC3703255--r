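#' Parse an Enzyme Commission number
#'
#' An EC number has four components, each a positive integer or the missing
#' marker `"-"`. Incomplete numbers (any `"-"` component) are legal and common
#' in pathway databases; they are *never* treated as wildcards by the matching
#' rules, only compared literally.
#'
#' @param x Character vector of EC texts, e.g. `"2.7.4.14"`, `"2.4.2.-"`.
#' @return A character matrix with four columns (`ec1`..`ec4`), one row per
#'   input, components canonicalized (no leading zeros). Invalid inputs raise
#'   an error.
#' @examples
#' ec_parse("2.4.2.-")
#' @export
ec_parse <- function(x) {
  stopifnot(is.character(x))
  parts <- stringr::str_split(stringr::str_trim(x), stringr::fixed("."))
  bad <- vapply(parts, function(p) {
    length(p) != 4L || !all(p == "-" | grepl("^[0-9]+$", p)) ||
      any(p != "-" & suppressWarnings(as.integer(p)) < 1L)
  }, logical(1))
  if (any(bad)) {
    abort(paste0("malformed EC number(s): ", paste(unique(x[bad]), collapse = ", ")),
          class = "c2_parse_error")
  }
  m <- t(vapply(parts, function(p) {
    ifelse(p == "-", "-", as.character(suppressWarnings(as.integer(p))))
  }, character(4)))
  colnames(m) <- paste0("ec", 1:4)
  m
}

#' Format parsed EC components back to text
#'
#' Round-trips exactly with [ec_parse()].
#' @param m Matrix as returned by [ec_parse()].
#' @return Character vector of EC texts.
#' @export
ec_format <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  apply(m, 1, paste, collapse = ".")
}

# canonical text form (validates and strips leading zeros)
ec_canonical <- function(x) ec_format(ec_parse(x))

#' Literal EC equality
#'
#' Two EC numbers are equal iff all four components are identical. The missing
#' marker `"-"` is matched literally, not as a wildcard: `2.4.2.-` does not
#' equal `2.4.2.1`, but `1.-.-.-` equals `1.-.-.-`.
#'
#' @param e1,e2 Character vectors of EC texts (recycled).
#' @return Logical vector.
#' @export
ec_equal <- function(e1, e2) {
  ec_canonical(e1) == ec_canonical(e2)
}

#' EC equality up to the fourth component
#'
#' True iff the first three components are identical and none of them is
#' missing. The fourth component distinguishes substrate specificities only,
#' so a relaxed query ("wider net") may ignore it.
#'
#' @inheritParams ec_equal
#' @return Logical vector; `FALSE` whenever any of the first three components
#'   of either number is `"-"`.
#' @export
ec_family_equal <- function(e1, e2) {
  m1 <- ec_parse(e1)
  m2 <- ec_parse(e2)
  n <- max(nrow(m1), nrow(m2))
  i1 <- rep_len(seq_len(nrow(m1)), n)
  i2 <- rep_len(seq_len(nrow(m2)), n)
  ok1 <- rowSums(m1[i1, 1:3, drop = FALSE] == "-") == 0L
  ok2 <- rowSums(m2[i2, 1:3, drop = FALSE] == "-") == 0L
  same <- rowSums(m1[i1, 1:3, drop = FALSE] == m2[i2, 1:3, drop = FALSE]) == 3L
  ok1 & ok2 & same
}
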