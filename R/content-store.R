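#' Local content-addressable store
#'
#' A flat-directory store in which immutable byte payloads are written once
#' and retrieved by the lowercase-hex SHA-256 digest of their bytes, emulating
#' the off-chain half of a content-addressed data commons. Files live under
#' `<path>/<aa>/<digest>` where `aa` is the first two digest characters
#' (fan-out keeps directories small); optional media hints are recorded in a
#' JSON sidecar index next to the payload tree.
#'
#' @param path Directory to hold the store (created if absent).
#' @return An object of class `content_store`.
#' @examples
#' st <- content_store(file.path(tempdir(), "store-demo"))
#' addr <- store_put(st, "abc")
#' rawToChar(store_get(st, addr))
#' @export
content_store <- function(path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    stop(errorCondition(paste0("cannot create store at ", path),
                        class = c("genetrust_io_error", "genetrust_error")))
  }
  structure(list(path = normalizePath(path)), class = "content_store")
}

#' @export
print.content_store <- function(x, ...) {
  cat("<content_store> ", x$path, " (", store_size(x), " objects)\n", sep = "")
  invisible(x)
}

#' SHA-256 digest of a byte payload, as 64 lowercase hex characters
#'
#' @param payload Raw vector, or a single string taken as its UTF-8 bytes.
#' @return Content address (character scalar).
#' @export
sha256_hex <- function(payload) {
  digest::digest(as_payload(payload), algo = "sha256", serialize = FALSE)
}

#' Store a payload and return its content address
#'
#' Identical bytes are stored once: re-putting is a no-op that returns the
#' same address.
#'
#' @param store A [content_store()].
#' @param payload Raw vector (a string is taken as UTF-8 bytes; empty allowed).
#' @param media_hint Optional label (e.g. `"omop-json"`) kept in the sidecar
#'   index; purely advisory.
#' @return The content address of `payload`.
#' @export
store_put <- function(store, payload, media_hint = NULL) {
  payload <- as_payload(payload)
  address <- sha256_hex(payload)
  dest <- object_path(store, address)
  if (!file.exists(dest)) {
    dir.create(dirname(dest), showWarnings = FALSE)
    tmp <- tempfile(tmpdir = store$path)
    writeBin(payload, tmp)
    file.rename(tmp, dest)
  }
  if (!is.null(media_hint)) {
    idx <- read_media_index(store)
    idx[[address]] <- as.character(media_hint)
    write_media_index(store, idx)
  }
  address
}

#' Retrieve a payload by content address
#'
#' @inheritParams store_put
#' @param address A 64-character lowercase hex digest.
#' @return The stored raw payload.
#' @export
store_get <- function(store, address) {
  assert_address(address)
  dest <- object_path(store, address)
  if (!file.exists(dest)) {
    stop(errorCondition(paste0("no object stored at address ", address),
                        class = c("genetrust_not_found", "genetrust_error")))
  }
  readBin(dest, "raw", n = file.size(dest))
}

#' @rdname store_get
#' @export
store_exists <- function(store, address) {
  assert_address(address)
  file.exists(object_path(store, address))
}

#' Check a payload against a content address
#'
#' @param address Claimed content address.
#' @param payload Bytes to check.
#' @return `TRUE` iff the SHA-256 of `payload` equals `address`.
#' @export
verify_address <- function(address, payload) {
  is_content_address(address) && identical(sha256_hex(payload), address)
}

#' @rdname verify_address
#' @export
is_content_address <- function(address) {
  is.character(address) && length(address) == 1L && !is.na(address) &&
    grepl("^[0-9a-f]{64}$", address)
}

#' Number of objects in a store
#' @inheritParams store_put
#' @export
store_size <- function(store) {
  length(list.files(store$path, pattern = "^[0-9a-f]{64}$", recursive = TRUE))
}

#' Media hint recorded for an address, or `NA` if none
#' @inheritParams store_get
#' @export
store_media_hint <- function(store, address) {
  assert_address(address)
  idx <- read_media_index(store)
  if (is.null(idx[[address]])) NA_character_ else idx[[address]]
}

as_payload <- function(payload) {
  if (is.character(payload) && length(payload) == 1L) {
    payload <- charToRaw(enc2utf8(payload))
  }
  if (!is.raw(payload)) {
    stop(errorCondition("payload must be a raw vector or a single string",
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  payload
}

assert_address <- function(address) {
  if (!is_content_address(address)) {
    stop(errorCondition(
      paste0("malformed content address: ",
             if (is.character(address) && length(address) == 1L) address
             else paste0("<", class(address)[1L], ">")),
      class = c("genetrust_malformed_address", "genetrust_error")))
  }
  invisible(address)
}

object_path <- function(store, address) {
  file.path(store$path, substr(address, 1, 2), address)
}

media_index_path <- function(store) file.path(store$path, "media-index.json")

read_media_index <- function(store) {
  p <- media_index_path(store)
  if (!file.exists(p)) return(list())
  jsonlite::fromJSON(p, simplifyVector = FALSE)
}

write_media_index <- function(store, idx) {
  tmp <- tempfile(tmpdir = store$path)
  writeLines(jsonlite::toJSON(idx, auto_unbox = TRUE), tmp)
  file.rename(tmp, media_index_path(store))
}
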