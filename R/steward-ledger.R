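#' Open (or create) a steward ledger
#'
#' A ledger couples a [content_store()] with per-steward ordered submission
#' lists, a steward registry, and an append-only anchor log that simulates
#' the on-chain provenance record: after every submission the steward's
#' top-level hash -- the SHA-256 of the canonicalized ordered list of
#' submission addresses -- is appended to the log with a strictly increasing
#' sequence number. Anchor entries are never mutated or deleted, so the log
#' after n submissions is a prefix of the log after n+1.
#'
#' On-disk layout under `path`: `store/` (the content store),
#' `stewards.json` (registry), `state/<steward>.json` (ordered address
#' lists) and `anchors.ndjson` (newline-delimited anchor records carrying
#' sequence, steward, top hash and a wall-clock timestamp; timestamps live
#' only here, never in hashed material).
#'
#' @param path Ledger root directory.
#' @return Object of class `cgt_ledger`.
#' @export
cgt_ledger <- function(path) {
  dir.create(file.path(path, "state"), recursive = TRUE, showWarnings = FALSE)
  st <- content_store(file.path(path, "store"))
  reg_path <- file.path(path, "stewards.json")
  if (!file.exists(reg_path)) {
    writeLines("{}", reg_path)
  }
  structure(list(path = normalizePath(path), store = st),
            class = "cgt_ledger")
}

#' @export
print.cgt_ledger <- function(x, ...) {
  cat("<cgt_ledger> ", x$path, "\n  stewards: ",
      paste(names(read_stewards(x)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Register a steward
#'
#' @param ledger A [cgt_ledger()].
#' @param identifier Unique steward identifier (e.g. an institution short
#'   name); non-empty.
#' @param display_name Human-readable name.
#' @return The identifier, invisibly.
#' @export
register_steward <- function(ledger, identifier, display_name = identifier) {
  if (!is.character(identifier) || length(identifier) != 1L ||
      !nzchar(identifier)) {
    stop(errorCondition("steward identifier must be non-empty text",
                        class = c("genetrust_id_error", "genetrust_error")))
  }
  reg <- read_stewards(ledger)
  reg[[identifier]] <- list(display_name = display_name)
  writeLines(jsonlite::toJSON(reg, auto_unbox = TRUE),
             file.path(ledger$path, "stewards.json"))
  invisible(identifier)
}

read_stewards <- function(ledger) {
  jsonlite::fromJSON(file.path(ledger$path, "stewards.json"),
                     simplifyVector = FALSE)
}

assert_steward <- function(ledger, steward) {
  if (is.null(read_stewards(ledger)[[steward]])) {
    stop(errorCondition(paste0("unknown steward: ", steward),
                        class = c("genetrust_id_error", "genetrust_error")))
  }
  invisible(steward)
}

#' Construct a submission manifest
#'
#' A submission is a per-patient manifest of deidentified scalar fields plus
#' named file references (content addresses), tagged by modality. The
#' manifest never embeds the referenced bytes; it points at them by hash, so
#' the submission address covers the file contents indirectly
#' (Merkle-style).
#'
#' @param patient_id UUID-4 text.
#' @param fields Named list of deidentified scalar fields.
#' @param files Named list/character of content addresses.
#' @param tags Modality tags, subset of
#'   `c("clinical-registry", "clinical-omop", "genomic", "imaging")`.
#' @return Object of class `cgt_submission`.
#' @export
submission <- function(patient_id, fields = list(), files = list(),
                       tags = character(0)) {
  if (!is_uuid4(patient_id)) {
    stop(errorCondition(paste0("not a UUID-4 patient id: ", patient_id),
                        class = c("genetrust_id_error", "genetrust_error")))
  }
  bad_tags <- setdiff(tags, c("clinical-registry", "clinical-omop",
                              "genomic", "imaging"))
  if (length(bad_tags)) {
    stop(errorCondition(paste0("unknown modality tag: ",
                               paste(bad_tags, collapse = ", ")),
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  files <- as.list(files)
  structure(list(patient_id = patient_id, fields = fields, files = files,
                 tags = sort(unique(as.character(tags)))),
            class = "cgt_submission")
}

submission_document <- function(sub) {
  list(patient_id = sub$patient_id,
       fields = if (length(sub$fields)) sub$fields
                else structure(list(), names = character(0)),
       files = if (length(sub$files)) sub$files
               else structure(list(), names = character(0)),
       tags = as.list(sub$tags))
}

#' Submit a manifest under a steward
#'
#' The manifest is gated through [phi_scan()] (any finding rejects the
#' submission), its file references are checked to resolve in the store,
#' and the canonical manifest bytes are stored. The submission's address is
#' appended to the steward's ordered list, the new top-level hash is
#' computed, and an anchor entry is appended to the log.
#'
#' @param ledger A [cgt_ledger()].
#' @param steward Registered steward identifier.
#' @param sub A [submission()].
#' @param config A [deid_config()] for the PHI gate.
#' @return List with `address` (the submission's content address),
#'   `top_hash`, and `sequence` (the anchor sequence number).
#' @export
submit <- function(ledger, steward, sub, config = deid_config()) {
  assert_steward(ledger, steward)
  stopifnot(inherits(sub, "cgt_submission"))
  doc <- submission_document(sub)
  findings <- phi_scan(doc, config)
  if (nrow(findings)) {
    stop(errorCondition(
      paste0("submission rejected, PHI findings: ",
             paste(findings$category, "at", findings$location,
                   collapse = "; ")),
      class = c("genetrust_phi_error", "genetrust_error")))
  }
  for (addr in unlist(doc$files)) {
    if (!store_exists(ledger$store, addr)) {
      stop(errorCondition(
        paste0("submission rejected, dangling file reference: ", addr),
        class = c("genetrust_not_found", "genetrust_error")))
    }
  }
  address <- store_put(ledger$store, canonicalize(doc),
                       media_hint = "submission-manifest")
  addrs <- c(read_steward_state(ledger, steward), address)
  write_steward_state(ledger, steward, addrs)
  th <- hash_address_list(addrs)
  seq_no <- append_anchor(ledger, steward, th)
  list(address = address, top_hash = th, sequence = seq_no)
}

#' Current top-level hash for a steward
#'
#' SHA-256 of the canonicalized ordered list of the steward's submission
#' addresses; an empty list hashes the two bytes `[]`. Recomputable at any
#' time from the stored state.
#'
#' @inheritParams submit
#' @return Content address (character scalar).
#' @export
top_hash <- function(ledger, steward) {
  assert_steward(ledger, steward)
  hash_address_list(read_steward_state(ledger, steward))
}

hash_address_list <- function(addrs) {
  sha256_hex(canonicalize(as.list(addrs)))
}

state_path <- function(ledger, steward) {
  file.path(ledger$path, "state", paste0(steward, ".json"))
}

read_steward_state <- function(ledger, steward) {
  p <- state_path(ledger, steward)
  if (!file.exists(p)) return(character(0))
  unlist(jsonlite::fromJSON(p, simplifyVector = FALSE)) %||% character(0)
}

write_steward_state <- function(ledger, steward, addrs) {
  tmp <- tempfile(tmpdir = ledger$path)
  writeLines(rawToChar(canonicalize(as.list(addrs))), tmp)
  file.rename(tmp, state_path(ledger, steward))
}

anchor_path <- function(ledger) file.path(ledger$path, "anchors.ndjson")

append_anchor <- function(ledger, steward, th) {
  entries <- read_anchors(ledger)
  seq_no <- if (nrow(entries)) max(entries$sequence) + 1L else 1L
  rec <- list(sequence = seq_no, steward = steward, top_hash = th,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z",
                                 tz = "UTC"))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", sep = "",
      file = anchor_path(ledger), append = TRUE)
  seq_no
}

#' Read the anchor log
#' @inheritParams submit
#' @return Tibble with columns `sequence`, `steward`, `top_hash`,
#'   `timestamp`, in file order.
#' @export
read_anchors <- function(ledger) {
  p <- anchor_path(ledger)
  if (!file.exists(p)) {
    return(tibble::tibble(sequence = integer(0), steward = character(0),
                          top_hash = character(0), timestamp = character(0)))
  }
  lines <- readLines(p)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  tibble::tibble(
    sequence = vapply(recs, function(r) as.integer(r$sequence), integer(1)),
    steward = vapply(recs, function(r) r$steward, character(1)),
    top_hash = vapply(recs, function(r) r$top_hash, character(1)),
    timestamp = vapply(recs, function(r) r$timestamp %||% NA_character_,
                       character(1))
  )
}

#' Verify a steward's provenance chain
#'
#' Checks, without raising, that (a) every listed submission address
#' resolves and its stored bytes re-hash to the address, and every file the
#' manifest references does too; (b) the top hash recomputed from the
#' current submission list equals the steward's latest anchor entry; and
#' (c) anchor sequence numbers are strictly increasing. Any single tampered
#' byte reachable from the top hash flips the report to not-ok.
#'
#' @inheritParams submit
#' @return List with `ok` (logical) and `failures` (character vector of
#'   messages naming the offending address or entry).
#' @export
verify_provenance <- function(ledger, steward) {
  assert_steward(ledger, steward)
  failures <- character(0)
  addrs <- read_steward_state(ledger, steward)
  for (addr in addrs) {
    if (!store_exists(ledger$store, addr)) {
      failures <- c(failures, paste0("missing submission object ", addr))
      next
    }
    payload <- store_get(ledger$store, addr)
    if (!verify_address(addr, payload)) {
      failures <- c(failures, paste0("submission ", addr,
                                     " fails re-hash (tampered payload)"))
      next
    }
    doc <- tryCatch(parse_canonical(payload), error = function(e) NULL)
    if (is.null(doc)) {
      failures <- c(failures, paste0("submission ", addr, " is unparseable"))
      next
    }
    for (faddr in unlist(doc$files)) {
      if (!store_exists(ledger$store, faddr)) {
        failures <- c(failures, paste0("submission ", addr,
                                       " references missing file ", faddr))
      } else if (!verify_address(faddr, store_get(ledger$store, faddr))) {
        failures <- c(failures, paste0("file ", faddr,
                                       " fails re-hash (tampered payload)"))
      }
    }
  }
  anchors <- read_anchors(ledger)
  mine <- anchors[anchors$steward == steward, , drop = FALSE]
  if (length(addrs)) {
    expected <- hash_address_list(addrs)
    if (nrow(mine) == 0L) {
      failures <- c(failures, "no anchor entry for steward with submissions")
    } else if (mine$top_hash[nrow(mine)] != expected) {
      failures <- c(failures,
                    paste0("latest anchored top hash ",
                           mine$top_hash[nrow(mine)],
                           " does not match recomputed ", expected))
    }
  }
  if (nrow(anchors) > 1L && any(diff(anchors$sequence) <= 0L)) {
    failures <- c(failures, "anchor sequence numbers are not strictly increasing")
  }
  list(ok = length(failures) == 0L, failures = failures)
}

#' List a steward's submissions
#'
#' @inheritParams submit
#' @param tags Optional modality filter: submissions whose tag set
#'   intersects `tags` are kept.
#' @return List of `cgt_submission` objects in append order.
#' @export
list_submissions <- function(ledger, steward, tags = NULL) {
  assert_steward(ledger, steward)
  addrs <- read_steward_state(ledger, steward)
  subs <- lapply(addrs, function(addr) {
    doc <- parse_canonical(store_get(ledger$store, addr))
    submission(doc$patient_id, fields = doc$fields, files = doc$files,
               tags = unlist(doc$tags) %||% character(0))
  })
  if (!is.null(tags)) {
    keep <- vapply(subs, function(s) length(intersect(s$tags, tags)) > 0L,
                   logical(1))
    subs <- subs[keep]
  }
  subs
}
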