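#' Canonical JSON serialization
#'
#' Serializes a structured document to a deterministic JSON byte sequence so
#' that equal documents always hash to equal content addresses, regardless of
#' the order in which map keys were inserted or of platform formatting
#' defaults. The dialect is fixed: object keys sorted lexicographically by
#' Unicode code point, no insignificant whitespace, UTF-8 encoding, and
#' numbers rendered in their shortest decimal form that round-trips to the
#' same double.
#'
#' The document model maps onto R as follows: `NULL` is JSON `null`; a
#' length-one logical, numeric, or character vector is a JSON scalar; an
#' atomic vector of any other length is an array of scalars; a named list is
#' an object (all elements must be named, names unique); an unnamed list is
#' an array. An empty list with a `names` attribute (as produced by
#' [parse_canonical()] for `{}`) is an empty object; a bare `list()` is `[]`.
#'
#' @param document A structured document (see Details).
#' @return A raw vector of UTF-8 encoded JSON bytes.
#' @examples
#' rawToChar(canonicalize(list(b = 1, a = 2)))  # keys reordered: a before b
#' @seealso [parse_canonical()] for the inverse, [store_put()] for hashing.
#' @export
canonicalize <- function(document) {
  charToRaw(canonical_chunk(document))
}

#' Parse canonical JSON bytes back into the document model
#'
#' @param bytes Raw vector (or single string) of JSON text.
#' @return The document as nested R lists; scalars stay length-one vectors.
#' @export
parse_canonical <- function(bytes) {
  if (is.raw(bytes)) bytes <- rawToChar(bytes)
  jsonlite::fromJSON(bytes, simplifyVector = FALSE)
}

canonical_chunk <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm) && length(x) == 0L) return("[]")
    if (is.null(nm)) {
      return(paste0("[", paste(vapply(x, canonical_chunk, character(1)),
                               collapse = ","), "]"))
    }
    if (length(x) == 0L) return("{}")
    if (anyNA(nm) || any(nm == "")) {
      stop(canonical_error("map keys must all be non-empty text"))
    }
    if (anyDuplicated(nm)) {
      stop(canonical_error("duplicate map key: ", nm[duplicated(nm)][1L]))
    }
    ord <- order_codepoint(nm)
    parts <- vapply(ord, function(i) {
      paste0(canonical_string(nm[i]), ":", canonical_chunk(x[[i]]))
    }, character(1))
    return(paste0("{", paste(parts, collapse = ","), "}"))
  }
  if (length(x) != 1L) {
    # atomic vector that is not a scalar: array of scalars
    return(paste0("[", paste(vapply(seq_along(x), function(i)
      canonical_chunk(x[i]), character(1)), collapse = ","), "]"))
  }
  if (is.na(x)) stop(canonical_error("NA is not representable"))
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) return(canonical_number(x))
  if (is.character(x)) return(canonical_string(x))
  stop(canonical_error("unsupported value of class ", class(x)[1L]))
}

# Shortest decimal representation that parses back to the same double.
canonical_number <- function(x) {
  x <- as.double(x)
  if (!is.finite(x)) stop(canonical_error("non-finite number"))
  if (x == floor(x) && abs(x) < 2^53) {
    return(sprintf("%.0f", x))
  }
  for (d in 1:17) {
    s <- sprintf(paste0("%.", d, "g"), x)
    if (as.double(s) == x) return(s)
  }
  sprintf("%.17g", x)  # unreachable: 17 significant digits always round-trip
}

canonical_string <- function(s) {
  s <- enc2utf8(as.character(s))
  cps <- utf8ToInt(s)
  if (is.na(cps[1]) && nzchar(s)) stop(canonical_error("invalid UTF-8 text"))
  out <- vapply(cps, function(cp) {
    if (cp == 0x22) return("\\\"")
    if (cp == 0x5C) return("\\\\")
    if (cp >= 0x20) return(intToUtf8(cp))
    switch(as.character(cp),
      "8"  = "\\b", "9" = "\\t", "10" = "\\n", "12" = "\\f", "13" = "\\r",
      sprintf("\\u%04x", cp))
  }, character(1))
  paste0("\"", paste(out, collapse = ""), "\"")
}

# Lexicographic by code point: radix sort uses C-locale byte order, which for
# UTF-8 coincides with code-point order.
order_codepoint <- function(nm) {
  order(enc2utf8(nm), method = "radix")
}

canonical_error <- function(...) {
  errorCondition(paste0("canonicalization error: ", ...),
                 class = c("genetrust_canonical_error", "genetrust_error"))
}
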