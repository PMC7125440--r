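#' Scan a document for residual protected health information
#'
#' A regex-based leak detector run as a gate before any submission: it walks
#' a structured document (nested lists, tibbles, data frames) and reports a
#' finding for every date literal (ISO `YYYY-MM-DD`, US `MM/DD/YYYY`, or
#' month-name dates), SSN-, phone- or email-shaped string, 7-9 digit bare
#' integer stored under a medical-record-style key, person-name field, or
#' deny-listed key. An empty result means the document passes the gate.
#'
#' This is a heuristic screen designed to catch the identifier shapes the
#' pipeline itself could leak; it is not a certified deidentification audit
#' and does not replace expert review of free text.
#'
#' @param document Nested list / tibble / scalar document.
#' @param config A [deid_config()] supplying the key deny-list.
#' @return Tibble with columns `location` (a path such as
#'   `registry.chemo_text`), `category` and `excerpt` (matched text,
#'   truncated). Zero rows means no findings.
#' @export
phi_scan <- function(document, config = deid_config()) {
  findings <- scan_node(document, "", config)
  if (!length(findings)) {
    return(tibble::tibble(location = character(0), category = character(0),
                          excerpt = character(0)))
  }
  tibble::as_tibble(do.call(rbind, lapply(findings, as.data.frame,
                                          stringsAsFactors = FALSE)))
}

scan_node <- function(node, path, config) {
  if (is.null(node)) return(list())
  if (is.data.frame(node)) {
    out <- list()
    for (i in seq_len(nrow(node))) {
      row <- as.list(node[i, ])
      out <- c(out, scan_node(row, paste0(path, "[", i, "]"), config))
    }
    return(out)
  }
  if (is.list(node)) {
    nm <- names(node)
    out <- list()
    for (i in seq_along(node)) {
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else NULL
      sub_path <- if (is.null(key)) {
        paste0(path, "[", i, "]")
      } else if (nzchar(path)) {
        paste0(path, ".", key)
      } else {
        key
      }
      if (!is.null(key)) {
        out <- c(out, scan_key(key, node[[i]], sub_path, config))
      }
      out <- c(out, scan_node(node[[i]], sub_path, config))
    }
    return(out)
  }
  # atomic leaf (possibly a vector)
  out <- list()
  vals <- node[!is.na(node)]
  for (v in vals) {
    out <- c(out, scan_value(v, path))
  }
  out
}

scan_key <- function(key, value, path, config) {
  out <- list()
  k <- tolower(key)
  if (k %in% config$deny_keys) {
    out <- c(out, list(finding(path, "denied-key", key)))
  } else if (grepl("(^|[._-])name$", k)) {
    out <- c(out, list(finding(path, "name-field", key)))
  }
  if (is.atomic(value) &&
      grepl("mrn|medical[._-]?record|chart[._-]?(number|no|num)|record[._-]?(number|no)|account[._-]?(number|no)", k)) {
    for (v in value[!is.na(value)]) {
      if (grepl("^[0-9]{7,9}$", trimws(as.character(v)))) {
        out <- c(out, list(finding(path, "mrn-like", as.character(v))))
      }
    }
  }
  out
}

scan_value <- function(v, path) {
  if (!is.character(v)) return(list())
  out <- list()
  for (cat in names(phi_value_patterns)) {
    m <- regmatches(v, regexpr(phi_value_patterns[[cat]], v, perl = TRUE))
    if (length(m) && nzchar(m)) {
      out <- c(out, list(finding(path, cat, m)))
    }
  }
  out
}

finding <- function(location, category, excerpt) {
  list(location = location, category = category,
       excerpt = substr(excerpt, 1, 40))
}

phi_month_re <- paste0(
  "(Jan(uary)?|Feb(ruary)?|Mar(ch)?|Apr(il)?|May|Jun(e)?|Jul(y)?|",
  "Aug(ust)?|Sep(t(ember)?)?|Oct(ober)?|Nov(ember)?|Dec(ember)?)")

phi_value_patterns <- list(
  "date-literal" = paste0(
    "\\b[0-9]{4}-[0-9]{2}-[0-9]{2}\\b",
    "|\\b[0-9]{1,2}/[0-9]{1,2}/[0-9]{4}\\b",
    "|\\b", phi_month_re, "\\.?\\s+[0-9]{1,2}(st|nd|rd|th)?,?\\s+[0-9]{4}\\b",
    "|\\b[0-9]{1,2}\\s+", phi_month_re, "\\.?,?\\s+[0-9]{4}\\b"),
  "ssn-like"   = "\\b[0-9]{3}-[0-9]{2}-[0-9]{4}\\b",
  "phone-like" = "\\([0-9]{3}\\)\\s*[0-9]{3}[-. ][0-9]{4}|\\b[0-9]{3}[-.][0-9]{3}[-.][0-9]{4}\\b",
  "email-like" = "[A-Za-z0-9._%+-]+@[A-Za-z0-9.-]+\\.[A-Za-z]{2,}"
)
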