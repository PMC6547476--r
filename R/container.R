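# Binary archive container: a fixed header plus the per-stream payloads,
# with enough metadata (codec parameters, checksums) for exact inversion and
# integrity attribution.  All integers little-endian fixed-width; 64-bit
# fields carried as 8 raw bytes (values are exact doubles below 2^53).

ARCHIVE_MAGIC <- charToRaw("FQCMARC1")
ARCHIVE_VERSION <- 1L

STREAM_NAMES <- c("identifiers", "sequences", "lengths", "qualities", "plus")
STREAM_IDS <- c(identifiers = 1L, sequences = 2L, lengths = 3L,
                qualities = 4L, plus = 5L)
CODEC_IDS <- c(fcm_identifier = 1L, fcm_sequence = 2L, fcm_bytes = 3L,
               cm_quality = 4L)

u32_to_raw <- function(x) {
  x <- as.numeric(x)
  stopifnot(x >= 0, x < 2^32)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

raw_to_u32 <- function(r) {
  sum(as.numeric(r[1:4]) * c(1, 256, 65536, 16777216))
}

u64_to_raw <- function(x) {
  x <- as.numeric(x)
  stopifnot(x >= 0, x < 2^53)
  lo <- x %% 2^32
  hi <- x %/% 2^32
  c(u32_to_raw(lo), u32_to_raw(hi))
}

raw_to_u64 <- function(r) {
  raw_to_u32(r[1:4]) + raw_to_u32(r[5:8]) * 2^32
}

serialize_config <- function(config) {
  charToRaw(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
}

deserialize_config <- function(bytes) {
  x <- jsonlite::fromJSON(rawToChar(bytes))
  do.call(fq_codec_config, x)
}

#' Write a compression archive
#'
#' Packs the per-stream payloads into a single binary archive: an 8-byte
#' magic tag, format version, flags (newline style, plus-line mode), record
#' count, a whole-file checksum of the original FASTQ bytes, and one entry
#' per stream (stream id, codec id, codec parameter block, payload length,
#' checksum of the uncompressed stream bytes, checksum of the compressed
#' payload bytes) followed by the payloads in declared order.  The payload
#' checksum catches corruption that falls below the coder's symbol
#' resolution (e.g. in final flush bytes).  Payload offsets are derivable
#' from the header alone.
#'
#' @param meta List with `newline_style`, `plus_mode`, `record_count` and
#'   `file_checksum` (8 raw bytes).
#' @param streams Named list of stream entries, each a list with `payload`
#'   (raw), `codec` (name in `names(CODEC_IDS)` scope: one of
#'   `"fcm_identifier"`, `"fcm_sequence"`, `"fcm_bytes"`, `"cm_quality"`),
#'   `params` (raw codec parameter block) and `checksum` (8 raw bytes of the
#'   uncompressed stream).
#' @return A raw vector holding the archive.
#' @export
write_archive <- function(meta, streams) {
  stopifnot(all(names(streams) %in% STREAM_NAMES))
  flags <- (if (meta$newline_style == "CRLF") 1L else 0L) +
    4L * match(meta$plus_mode, c("BARE", "MIRROR", "VERBATIM")) - 4L
  header <- c(
    ARCHIVE_MAGIC,
    u32_to_raw(ARCHIVE_VERSION),
    u32_to_raw(flags),
    u64_to_raw(meta$record_count),
    meta$file_checksum,
    u32_to_raw(length(streams))
  )
  payloads <- raw(0)
  for (nm in names(streams)) {
    s <- streams[[nm]]
    header <- c(header,
                u32_to_raw(STREAM_IDS[[nm]]),
                u32_to_raw(CODEC_IDS[[s$codec]]),
                u32_to_raw(length(s$params)), s$params,
                u64_to_raw(length(s$payload)),
                s$checksum,
                fnv1a64_(s$payload))
    payloads <- c(payloads, s$payload)
  }
  c(header, payloads)
}

take_bytes <- function(bytes, pos, k, what) {
  if (k == 0) return(raw(0))
  if (pos + k - 1 > length(bytes)) {
    stop(sprintf("truncated archive while reading %s: expected %d bytes at offset %d, have %d",
                 what, k, pos - 1, length(bytes) - pos + 1))
  }
  bytes[pos:(pos + k - 1)]
}

#' Read a compression archive
#'
#' Parses the header and slices the payloads.  The magic tag and format
#' version are enforced; payload checksums are verified later, after each
#' stream decodes (see [fq_decompress()]), so corruption is attributed to
#' the stream it occurred in.
#'
#' @param x A raw vector or a file path.
#' @return A list with `meta` (newline style, plus mode, record count, file
#'   checksum) and `streams` (named list of `codec`, `params`, `payload`,
#'   `checksum`).
#' @export
read_archive <- function(x) {
  bytes <- if (is.raw(x)) x else readBin(x, "raw", n = file.info(x)$size)
  if (length(bytes) < 8L || !identical(bytes[1:8], ARCHIVE_MAGIC)) {
    stop("not an archive: bad magic tag")
  }
  pos <- 9L
  rd <- function(k, what) {
    out <- take_bytes(bytes, pos, k, what)
    pos <<- pos + as.integer(k)
    out
  }
  version <- raw_to_u32(rd(4L, "version"))
  if (version != ARCHIVE_VERSION) {
    stop(sprintf("unsupported archive version %d (this build reads version %d)",
                 version, ARCHIVE_VERSION))
  }
  flags <- raw_to_u32(rd(4L, "flags"))
  newline_style <- if (flags %% 2 == 1) "CRLF" else "LF"
  plus_mode <- c("BARE", "MIRROR", "VERBATIM")[(flags %/% 4) %% 4 + 1]
  record_count <- raw_to_u64(rd(8L, "record count"))
  file_checksum <- rd(8L, "file checksum")
  n_streams <- raw_to_u32(rd(4L, "stream count"))
  entries <- vector("list", n_streams)
  names_v <- character(n_streams)
  for (i in seq_len(n_streams)) {
    sid <- raw_to_u32(rd(4L, "stream id"))
    nm <- names(STREAM_IDS)[match(sid, STREAM_IDS)]
    if (is.na(nm)) stop(sprintf("unknown stream id %d", sid))
    cid <- raw_to_u32(rd(4L, "codec id"))
    cnm <- names(CODEC_IDS)[match(cid, CODEC_IDS)]
    if (is.na(cnm)) stop(sprintf("unknown codec id %d for stream '%s'", cid, nm))
    plen <- raw_to_u32(rd(4L, "parameter block length"))
    params <- rd(plen, sprintf("parameter block of stream '%s'", nm))
    paylen <- raw_to_u64(rd(8L, sprintf("payload length of stream '%s'", nm)))
    checksum <- rd(8L, sprintf("checksum of stream '%s'", nm))
    payload_checksum <- rd(8L, sprintf("payload checksum of stream '%s'", nm))
    entries[[i]] <- list(codec = cnm, params = params,
                         payload_length = paylen, checksum = checksum,
                         payload_checksum = payload_checksum)
    names_v[i] <- nm
  }
  for (i in seq_len(n_streams)) {
    entries[[i]]$payload <- rd(entries[[i]]$payload_length,
                               sprintf("payload of stream '%s'", names_v[i]))
    entries[[i]]$payload_length <- NULL
  }
  if (pos - 1L != length(bytes)) {
    stop(sprintf("archive has %d trailing byte(s) after declared payloads",
                 length(bytes) - pos + 1L))
  }
  names(entries) <- names_v
  list(
    meta = list(newline_style = newline_style, plus_mode = plus_mode,
                record_count = record_count, file_checksum = file_checksum),
    streams = entries
  )
}
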