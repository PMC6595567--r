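#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Classed error helpers ---------------------------------------------------

stop_rm5 <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "rm5_error"), ...)
}

#' Strip inline markup from a free-text field
#'
#' Characteristics fields keep their raw inline markup (paragraph and emphasis
#' tags) in the model so that files round-trip losslessly. Matching and
#' normalisation work on a plain-text projection instead: tags stripped,
#' XML entities decoded, whitespace collapsed.
#'
#' @param x Character vector of raw field content (possibly containing markup).
#' @return Character vector of the same length, plain text.
#' @export
#' @examples
#' plain_text("<P>Allocation: <B>randomised</B>.</P>")
plain_text <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return("")
    if (!grepl("[<&]", s)) return(str_squish_ws(s))
    frag <- tryCatch(
      xml2::read_xml(paste0("<x>", s, "</x>")),
      error = function(e) NULL
    )
    if (is.null(frag)) return(str_squish_ws(s))
    str_squish_ws(xml2::xml_text(frag))
  }, character(1), USE.NAMES = FALSE)
}

str_squish_ws <- function(s) stringr::str_squish(s)

# XML canonicalization ----------------------------------------------------

xml_escape_text <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

xml_escape_attr <- function(s) {
  s <- xml_escape_text(s)
  gsub("\"", "&quot;", s, fixed = TRUE)
}

canonicalize_node <- function(node) {
  type <- class(node)[1]
  if (inherits(node, "xml_node")) {
    nm <- xml2::xml_name(node)
    attrs <- xml2::xml_attrs(node)
    attrs <- attrs[order(names(attrs))]
    attr_str <- if (length(attrs)) {
      paste0(" ", paste0(names(attrs), "=\"", xml_escape_attr(unname(attrs)), "\"", collapse = " "))
    } else ""
    kids <- xml2::xml_contents(node)
    inner <- character(0)
    for (i in seq_along(kids)) {
      k <- kids[[i]]
      kt <- xml2::xml_type(k)
      if (kt == "element") {
        inner <- c(inner, canonicalize_node(k))
      } else if (kt %in% c("text", "cdata")) {
        txt <- xml2::xml_text(k)
        if (nzchar(trimws(txt))) inner <- c(inner, xml_escape_text(txt))
      } else if (kt == "comment") {
        inner <- c(inner, paste0("<!--", xml2::xml_text(k), "-->"))
      }
    }
    if (length(inner)) {
      paste0("<", nm, attr_str, ">", paste0(inner, collapse = ""), "</", nm, ">")
    } else {
      paste0("<", nm, attr_str, "/>")
    }
  } else {
    ""
  }
}

#' Canonicalize an XML document for comparison
#'
#' Two serializations of the same document legitimately differ in byte layout
#' (attribute order, indentation, self-closing tags). Round-trip and write-back
#' contracts are therefore stated over canonical XML equality: attribute order
#' sorted, insignificant whitespace-only text nodes dropped, entities
#' re-escaped uniformly, comments preserved.
#'
#' @param x A file path, an XML string, or an `xml_document`.
#' @return A single canonical string.
#' @export
canonical_xml <- function(x) {
  doc <- if (inherits(x, "xml_document")) {
    x
  } else if (is.character(x) && length(x) == 1 && !grepl("^\\s*<", x)) {
    xml2::read_xml(x)
  } else {
    xml2::read_xml(paste(x, collapse = "\n"))
  }
  canonicalize_node(xml2::xml_root(doc))
}

#' Test two XML documents for canonical equality
#'
#' @param a,b File paths, XML strings, or `xml_document`s.
#' @return `TRUE` or `FALSE`.
#' @export
xml_canonical_equal <- function(a, b) {
  identical(canonical_xml(a), canonical_xml(b))
}

# Number formatting that survives a text round trip -----------------------

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (is.integer(v) || (is.numeric(v) && v == trunc(v) && abs(v) < 2^31)) {
      format(as.integer(v), scientific = FALSE)
    } else {
      sprintf("%.17g", v)
    }
  }, character(1), USE.NAMES = FALSE)
}

# Year parsing ------------------------------------------------------------

#' Parse a publication year from a study identifier
#'
#' Cochrane convention names studies "Surname YYYY" (with an optional trailing
#' letter disambiguating multiple studies, e.g. "Smith 1999a"). The rightmost
#' 4-digit token between 1800 and 2100, after stripping one trailing letter,
#' is taken as the year.
#'
#' @param study_id Character vector of study identifiers.
#' @return Integer vector, `NA` where no year token is present.
#' @export
#' @examples
#' parse_study_year(c("Smith 1999", "Perez 2003b", "NIMH Study"))
parse_study_year <- function(study_id) {
  vapply(study_id, function(s) {
    if (is.na(s)) return(NA_integer_)
    m <- gregexpr("(1[89]|20|21)[0-9]{2}(?=[a-z]?\\b)", s, perl = TRUE)[[1]]
    if (m[1] == -1) return(NA_integer_)
    tok <- substring(s, m, m + attr(m, "match.length") - 1)
    yr <- suppressWarnings(as.integer(tok[length(tok)]))
    if (!is.na(yr) && yr >= 1800 && yr <= 2100) yr else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}
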