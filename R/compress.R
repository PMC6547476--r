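#' Compress a FASTQ file into a single binary archive
#'
#' The full pipeline: parse the 4-line records, decouple them into the four
#' streams, discard the plus-line stream when it is regenerable, compress
#' identifiers (tokenize + delta + byte FCMs), read lengths (delta + byte
#' FCM), sequences (competing FCMs) and qualities (context mixing), and pack
#' everything with checksums into one archive.  The codec configuration is
#' embedded in the archive so decompression is self-contained.
#'
#' @param input FASTQ bytes (raw vector) or a path to a FASTQ file.
#' @param output Optional path for the archive; if `NULL` the archive is
#'   returned as a raw vector in the bench record.
#' @param config An [fq_codec_config()].
#' @return Invisibly, a bench record list: input/output sizes (bytes),
#'   `ratio` (original/compressed), `seconds`, per-stream payload sizes and
#'   per-stream uncompressed sizes, and `archive` (raw) when `output` is
#'   `NULL`.
#' @examples
#' fx <- fq_generate(fq_generator_config(n_reads = 50, seed = 1))
#' rec <- fq_compress(fx)
#' rec$ratio > 1
#' @export
fq_compress <- function(input, output = NULL, config = fq_codec_config()) {
  t0 <- proc.time()[["elapsed"]]
  raw_in <- as_fastq_raw(input)
  records <- parse_fastq(raw_in)
  bundle <- decouple(records)
  n <- bundle$record_count
  lengths <- nchar(bundle$sequences, type = "bytes")

  cfg_blob <- serialize_config(config)
  stream_raw <- list(
    identifiers = charToRaw(paste(bundle$identifiers, collapse = "\n")),
    sequences = charToRaw(paste(bundle$sequences, collapse = "\n")),
    lengths = u32s_to_raw(lengths),
    qualities = charToRaw(paste(bundle$qualities, collapse = "\n"))
  )
  enc_seq <- encode_sequences(bundle$sequences, config)
  enc_qual <- encode_qualities(bundle$qualities, config)
  streams <- list(
    identifiers = list(payload = encode_identifiers(bundle$identifiers),
                       codec = "fcm_identifier", params = raw(0),
                       checksum = fq_checksum(stream_raw$identifiers)),
    sequences = list(payload = enc_seq$payload, codec = "fcm_sequence",
                     params = cfg_blob,
                     checksum = fq_checksum(stream_raw$sequences)),
    lengths = list(payload = encode_lengths(lengths), codec = "fcm_bytes",
                   params = raw(0),
                   checksum = fq_checksum(stream_raw$lengths)),
    qualities = list(payload = enc_qual$payload, codec = "cm_quality",
                     params = cfg_blob,
                     checksum = fq_checksum(stream_raw$qualities))
  )
  if (bundle$plus_mode == "VERBATIM") {
    plus_raw <- charToRaw(paste(bundle$plus_payload, collapse = "\n"))
    streams$plus <- list(payload = fcm_bytes_encode_(plus_raw, 2L),
                         codec = "fcm_bytes",
                         params = u32_to_raw(length(plus_raw)),
                         checksum = fq_checksum(plus_raw))
  }
  meta <- list(newline_style = bundle$newline_style,
               plus_mode = bundle$plus_mode,
               record_count = n,
               file_checksum = fq_checksum(raw_in))
  archive <- write_archive(meta, streams)
  seconds <- proc.time()[["elapsed"]] - t0

  if (!is.null(output)) writeBin(archive, output)
  rec <- list(
    tool = "fqcm",
    input_bytes = length(raw_in),
    output_bytes = length(archive),
    ratio = compression_ratio(length(raw_in), length(archive)),
    seconds = seconds,
    stream_payload_bytes = vapply(streams, function(s) length(s$payload), numeric(1)),
    stream_raw_bytes = c(
      identifiers = sum(nchar(bundle$identifiers, type = "bytes")) +
        n * (1L + nl_width(bundle$newline_style)),
      sequences = sum(lengths) + n * nl_width(bundle$newline_style),
      qualities = sum(lengths) + n * nl_width(bundle$newline_style)
    ),
    archive = if (is.null(output)) archive else NULL
  )
  invisible(rec)
}

nl_width <- function(style) if (style == "CRLF") 2L else 1L

u32s_to_raw <- function(xs) {
  if (length(xs) == 0L) return(raw(0))
  do.call(c, lapply(xs, u32_to_raw))
}

#' Decompress an archive back to FASTQ bytes
#'
#' Exact inverse of [fq_compress()]: each stream is decoded with the codec
#' parameters recorded in the header, its checksum is verified (a mismatch
#' is attributed to that stream), the plus-line stream is regenerated from
#' its recorded mode, and the records are reassembled byte-identically.
#' The whole-file checksum is verified last.
#'
#' @param archive Raw archive bytes or a path to an archive file.
#' @param output Optional path for the FASTQ output; if `NULL` the bytes are
#'   returned.
#' @return The FASTQ bytes (invisibly when `output` is given).
#' @export
fq_decompress <- function(archive, output = NULL) {
  arc <- read_archive(archive)
  n <- arc$meta$record_count
  # every decode step runs under its stream's name so any corruption —
  # whether caught by the coder, a structural check or the checksum — is
  # attributed to the stream it occurred in
  with_stream <- function(nm, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("integrity error in stream '%s': %s", nm,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  check_stream <- function(nm, data) {
    if (!identical(fq_checksum(data), arc$streams[[nm]]$checksum)) {
      stop(sprintf("integrity error in stream '%s': checksum mismatch", nm),
           call. = FALSE)
    }
    data
  }
  # payload checksums first: corruption is caught even where it would not
  # change any decoded symbol (e.g. final flush bytes)
  for (nm in names(arc$streams)) {
    s <- arc$streams[[nm]]
    if (!identical(fq_checksum(s$payload), s$payload_checksum)) {
      stop(sprintf("integrity error in stream '%s': payload checksum mismatch", nm),
           call. = FALSE)
    }
  }
  lengths <- with_stream("lengths", {
    v <- decode_lengths(arc$streams$lengths$payload, n)
    check_stream("lengths", u32s_to_raw(v))
    v
  })
  config <- if (length(arc$streams$sequences$params)) {
    deserialize_config(arc$streams$sequences$params)
  } else {
    fq_codec_config()
  }
  ids_txt <- with_stream("identifiers", check_stream("identifiers",
    charToRaw(paste(decode_identifiers(arc$streams$identifiers$payload, n),
                    collapse = "\n"))))
  identifiers <- if (n == 0L) character() else
    strsplit(rawToChar(ids_txt), "\n", fixed = TRUE, useBytes = TRUE)[[1L]]
  # a trailing empty identifier would be dropped by strsplit; ids are non-empty
  sequences <- with_stream("sequences", {
    s <- decode_sequences(arc$streams$sequences$payload, lengths, config)
    check_stream("sequences", charToRaw(paste(s, collapse = "\n")))
    s
  })
  qualities <- with_stream("qualities", {
    q <- decode_qualities(arc$streams$qualities$payload, lengths, config)
    check_stream("qualities", charToRaw(paste(q, collapse = "\n")))
    q
  })
  plus_payload <- character()
  if (arc$meta$plus_mode == "VERBATIM") {
    plus_raw <- with_stream("plus", {
      nb <- raw_to_u32(arc$streams$plus$params)
      check_stream("plus", fcm_bytes_decode_(arc$streams$plus$payload, nb, 2L))
    })
    plus_payload <- if (n == 0L) character() else
      split_keep_empty(rawToChar(plus_raw), n)
  }
  bundle <- structure(list(
    identifiers = identifiers, sequences = sequences,
    plus_mode = arc$meta$plus_mode, plus_payload = plus_payload,
    qualities = qualities, record_count = n,
    newline_style = arc$meta$newline_style
  ), class = "fq_bundle")
  out <- reassemble(bundle)
  if (!identical(fq_checksum(out), arc$meta$file_checksum)) {
    stop("integrity error: whole-file checksum mismatch after reassembly")
  }
  if (!is.null(output)) {
    writeBin(out, output)
    return(invisible(out))
  }
  out
}

raw_to_u32s <- function(r) {
  n <- length(r) %/% 4L
  if (n == 0L) return(integer())
  m <- matrix(as.numeric(r), nrow = 4L)
  as.integer(m[1, ] + m[2, ] * 256 + m[3, ] * 65536 + m[4, ] * 16777216)
}

# split a joined string on \n into exactly n fields, keeping empty fields
split_keep_empty <- function(txt, n) {
  parts <- strsplit(txt, "\n", fixed = TRUE, useBytes = TRUE)[[1L]]
  # strsplit drops a trailing empty field; restore it
  if (length(parts) < n) parts <- c(parts, rep("", n - length(parts)))
  parts
}

#' Verify that an archive reproduces its original file exactly
#'
#' Decompresses to memory and byte-compares against the original — the
#' exact-replica criterion a lossless FASTQ tool must meet.  Never assumes:
#' the comparison is an actual byte comparison plus checksum agreement.
#'
#' @param archive Raw archive bytes or a path.
#' @param original Raw FASTQ bytes or a path.
#' @return `TRUE` if byte-identical; `FALSE` (with attribute `"reason"`)
#'   otherwise.
#' @export
fq_verify <- function(archive, original) {
  orig <- as_fastq_raw(original)
  out <- tryCatch(fq_decompress(archive), error = function(e) e)
  if (inherits(out, "error")) {
    return(structure(FALSE, reason = conditionMessage(out)))
  }
  if (!identical(out, orig)) {
    return(structure(FALSE, reason = "decompressed bytes differ from original"))
  }
  TRUE
}
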