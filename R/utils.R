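`%||%` <- function(x, y) if (is.null(x)) y else x

#' Seeded UUID-4 generation
#'
#' Draws 122 random bits from R's RNG and formats them as a version-4,
#' variant-10 UUID, so patient identifiers are reproducible under
#' `set.seed()` (the system UUID generator is not).
#'
#' @param n Number of identifiers.
#' @return Character vector of UUID-4 strings.
#' @export
ruuid4 <- function(n = 1L) {
  vapply(seq_len(n), function(i) {
    bytes <- sample.int(256L, 16L, replace = TRUE) - 1L
    bytes[7] <- bitwOr(bitwAnd(bytes[7], 0x0FL), 0x40L)  # version nibble 4
    bytes[9] <- bitwOr(bitwAnd(bytes[9], 0x3FL), 0x80L)  # variant bits 10
    hex <- paste(sprintf("%02x", bytes), collapse = "")
    paste(substr(hex, 1, 8), substr(hex, 9, 12), substr(hex, 13, 16),
          substr(hex, 17, 20), substr(hex, 21, 32), sep = "-")
  }, character(1))
}

# substream seed for patient i under master seed s; kept below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}
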