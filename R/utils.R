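#' @useDynLib omicspanel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Sniff the field delimiter of a delimited text file
#'
#' Candidate delimiters are comma, tab and semicolon; the winner is the one
#' that splits the header line into the most fields. Decimal point is always
#' ".".
#'
#' @param path file path.
#' @return single delimiter character.
#' @keywords internal
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stopf("empty file: %s", path)
  cands <- c(",", "\t", ";")
  counts <- vapply(cands, function(d) length(strsplit(header, d, fixed = TRUE)[[1L]]),
                   integer(1))
  cands[which.max(counts)]
}

## md5 of an in-memory object via its serialized bytes written to a temp file
## (used for config/provenance hashes; stable across sessions for plain lists)
object_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}

## seeds derived from a user seed must stay valid 32-bit integers
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647)
}
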