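#' Parse a 4-line FASTQ byte stream into records
#'
#' Strict 4-line FASTQ only: each record is an identifier line starting with
#' `@`, a sequence line, a plus-line starting with `+` (optionally followed by
#' a comment) and a quality line of the same length as the sequence.  Wrapped
#' (multi-line sequence) FASTQ is rejected.  The file must use a single
#' newline convention (LF or CRLF) throughout and end with a newline; these
#' rules are what make the compression round trip byte-exact.
#'
#' @param x A raw vector of FASTQ bytes, or a path to a FASTQ file.
#' @return A `data.frame` with character columns `identifier`, `sequence`,
#'   `plus` (the text after the `+`, possibly empty) and `quality`, one row
#'   per record, plus an attribute `newline_style` (`"LF"` or `"CRLF"`).
#'   Markers (`@`, `+`) are stripped and never stored.
#' @examples
#' parse_fastq(charToRaw("@r1\nACGT\n+\nIIII\n"))
#' @export
parse_fastq <- function(x) {
  raw <- as_fastq_raw(x)
  if (length(raw) == 0L) {
    return(empty_records("LF"))
  }
  txt <- rawToChar(raw)
  has_cr <- any(raw == as.raw(13L))
  if (has_cr) {
    # every CR must be followed by LF and every LF preceded by CR
    stripped <- gsub("\r\n", "", txt, fixed = TRUE, useBytes = TRUE)
    if (grepl("\r", stripped, fixed = TRUE, useBytes = TRUE) || grepl("\n", stripped, fixed = TRUE, useBytes = TRUE)) {
      stop("mixed newline conventions: lossless round trip cannot be guaranteed")
    }
    newline_style <- "CRLF"
    txt <- gsub("\r\n", "\n", txt, fixed = TRUE, useBytes = TRUE)
  } else {
    newline_style <- "LF"
  }
  nl_bytes <- if (newline_style == "CRLF") 2L else 1L
  if (substring(txt, nchar(txt), nchar(txt)) != "\n") {
    stop(sprintf("truncated trailing record: no final newline at byte offset %d",
                 length(raw)))
  }
  lines <- strsplit(txt, "\n", fixed = TRUE, useBytes = TRUE)[[1L]]
  n_lines <- length(lines)
  if (n_lines %% 4L != 0L) {
    complete <- n_lines %/% 4L
    offset <- sum(nchar(lines[seq_len(complete * 4L)], type = "bytes")) +
      complete * 4L * nl_bytes
    stop(sprintf("truncated trailing record: %d leftover line(s) starting at byte offset %d",
                 n_lines %% 4L, offset))
  }
  n <- n_lines %/% 4L
  ids <- lines[seq(1L, n_lines, by = 4L)]
  seqs <- lines[seq(2L, n_lines, by = 4L)]
  plus <- lines[seq(3L, n_lines, by = 4L)]
  quals <- lines[seq(4L, n_lines, by = 4L)]

  bad <- which(substring(ids, 1L, 1L) != "@")
  if (length(bad)) {
    stop(sprintf("record %d: identifier line does not start with '@' (wrapped FASTQ is not supported)",
                 bad[1L] - 1L))
  }
  bad <- which(substring(plus, 1L, 1L) != "+")
  if (length(bad)) {
    stop(sprintf("record %d: plus-line does not start with '+' (wrapped FASTQ is not supported)",
                 bad[1L] - 1L))
  }
  ids <- substring(ids, 2L)
  plus <- substring(plus, 2L)
  bad <- which(nchar(ids) == 0L)
  if (length(bad)) stop(sprintf("record %d: empty identifier", bad[1L] - 1L))
  ls <- nchar(seqs, type = "bytes")
  lq <- nchar(quals, type = "bytes")
  bad <- which(ls != lq)
  if (length(bad)) {
    stop(sprintf("quality length %d != sequence length %d at record %d",
                 lq[bad[1L]], ls[bad[1L]], bad[1L] - 1L))
  }
  bad <- which(grepl("[^\x21-\x7e]", seqs, perl = TRUE, useBytes = TRUE))
  if (length(bad)) stop(sprintf("record %d: sequence contains non-printable bytes", bad[1L] - 1L))
  bad <- which(grepl("[^\x21-\x7e]", quals, perl = TRUE, useBytes = TRUE))
  if (length(bad)) stop(sprintf("record %d: quality contains bytes outside ASCII 33-126", bad[1L] - 1L))

  records <- data.frame(identifier = ids, sequence = seqs, plus = plus,
                        quality = quals, stringsAsFactors = FALSE)
  attr(records, "newline_style") <- newline_style
  records
}

empty_records <- function(newline_style) {
  records <- data.frame(identifier = character(), sequence = character(),
                        plus = character(), quality = character(),
                        stringsAsFactors = FALSE)
  attr(records, "newline_style") <- newline_style
  records
}

as_fastq_raw <- function(x) {
  if (is.raw(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(readBin(x, "raw", n = file.info(x)$size))
  }
  stop("expected a raw vector or a file path")
}

#' Classify the plus-line stream of a set of FASTQ records
#'
#' The third FASTQ line is redundant in the overwhelmingly common cases: it is
#' either a bare `+` or `+` followed by a copy of the identifier.  Those two
#' cases are detected and the stream is discarded during compression and
#' regenerated at decompression.  Anything else falls back to storing the
#' plus-line comments verbatim, preserving losslessness on arbitrary input.
#'
#' @param records A record data frame from [parse_fastq()].
#' @return `"BARE"`, `"MIRROR"` or `"VERBATIM"`.
#' @export
classify_plus_lines <- function(records) {
  if (nrow(records) == 0L) return("BARE")
  if (all(records$plus == "")) return("BARE")
  if (all(records$plus == records$identifier)) return("MIRROR")
  "VERBATIM"
}

#' Decouple FASTQ records into the four per-field streams
#'
#' Field decoupling splits the records column-wise into homogeneous streams
#' (identifiers, sequences, plus-lines, qualities) so each can be compressed
#' with a stream-appropriate model.  The plus-line stream is kept only in
#' `VERBATIM` mode; in `BARE`/`MIRROR` mode it is regenerable and dropped.
#'
#' @param records A record data frame from [parse_fastq()].
#' @return A `fq_bundle` list: `identifiers`, `sequences`, `plus_mode`,
#'   `plus_payload` (empty unless `VERBATIM`), `qualities`, `record_count`,
#'   `newline_style`.
#' @export
decouple <- function(records) {
  plus_mode <- classify_plus_lines(records)
  bundle <- list(
    identifiers = records$identifier,
    sequences = records$sequence,
    plus_mode = plus_mode,
    plus_payload = if (plus_mode == "VERBATIM") records$plus else character(),
    qualities = records$quality,
    record_count = nrow(records),
    newline_style = attr(records, "newline_style") %||% "LF"
  )
  class(bundle) <- "fq_bundle"
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_bundle <- function(bundle) {
  n <- bundle$record_count
  stopifnot(
    is.numeric(n), n >= 0,
    length(bundle$identifiers) == n,
    length(bundle$sequences) == n,
    length(bundle$qualities) == n,
    bundle$plus_mode %in% c("BARE", "MIRROR", "VERBATIM"),
    bundle$newline_style %in% c("LF", "CRLF")
  )
  if (bundle$plus_mode == "VERBATIM") {
    stopifnot(length(bundle$plus_payload) == n)
  } else {
    stopifnot(length(bundle$plus_payload) == 0L)
  }
  if (n > 0 && any(nchar(bundle$qualities, type = "bytes") !=
                   nchar(bundle$sequences, type = "bytes"))) {
    stop("bundle invariant violated: quality/sequence length mismatch")
  }
  invisible(bundle)
}

#' Reassemble a FASTQ byte stream from a stream bundle
#'
#' Exact inverse of [parse_fastq()] + [decouple()]:
#' `reassemble(decouple(parse_fastq(x)))` is byte-identical to `x` for every
#' accepted input `x`.  Plus-lines are regenerated from `plus_mode`.
#'
#' @param bundle A `fq_bundle` from [decouple()] or [fq_decompress()].
#' @return A raw vector of FASTQ bytes.
#' @export
reassemble <- function(bundle) {
  validate_bundle(bundle)
  n <- bundle$record_count
  if (n == 0L) return(raw())
  plus_lines <- switch(bundle$plus_mode,
    BARE = rep("+", n),
    MIRROR = paste0("+", bundle$identifiers),
    VERBATIM = paste0("+", bundle$plus_payload)
  )
  lines <- character(4L * n)
  lines[seq(1L, 4L * n, by = 4L)] <- paste0("@", bundle$identifiers)
  lines[seq(2L, 4L * n, by = 4L)] <- bundle$sequences
  lines[seq(3L, 4L * n, by = 4L)] <- plus_lines
  lines[seq(4L, 4L * n, by = 4L)] <- bundle$qualities
  nl <- if (bundle$newline_style == "CRLF") "\r\n" else "\n"
  charToRaw(paste0(paste(lines, collapse = nl), nl))
}
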