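# Identifier stream codec: tokenize -> delta -> two byte streams (structural
# residuals, text literals) -> single finite-context models over bytes.

# growing raw buffer
new_bytebuf <- function() {
  buf <- raw(256L)
  n <- 0L
  list(
    add = function(bytes) {
      ln <- length(bytes)
      if (n + ln > length(buf)) {
        buf[max(2L * length(buf), n + ln)] <<- as.raw(0L)
      }
      if (ln) buf[(n + 1L):(n + ln)] <<- bytes
      n <<- n + ln
    },
    bytes = function() buf[seq_len(n)]
  )
}

varint_bytes <- function(v) {
  # LEB128 for non-negative doubles < 2^53
  out <- raw(0L)
  repeat {
    b <- v %% 128
    v <- (v - b) / 128
    if (v > 0) {
      out <- c(out, as.raw(b + 128))
    } else {
      out <- c(out, as.raw(b))
      return(out)
    }
  }
}

zigzag <- function(x) if (x >= 0) 2 * x else -2 * x - 1
unzigzag <- function(z) if (z %% 2 == 0) z / 2 else -(z + 1) / 2

# reader over a raw vector with position state
new_bytereader <- function(bytes) {
  pos <- 0L
  list(
    byte = function() {
      pos <<- pos + 1L
      if (pos > length(bytes)) stop("payload corrupt: out of bytes")
      as.integer(bytes[pos])
    },
    take = function(k) {
      if (k == 0L) return(raw(0L))
      if (pos + k > length(bytes)) stop("payload corrupt: out of bytes")
      out <- bytes[(pos + 1L):(pos + k)]
      pos <<- pos + k
      out
    },
    varint = function() {
      v <- 0
      mult <- 1
      repeat {
        pos <<- pos + 1L
        if (pos > length(bytes)) stop("payload corrupt: out of bytes")
        b <- as.integer(bytes[pos])
        v <- v + (b %% 128L) * mult
        if (b < 128L) return(v)
        mult <- mult * 128
      }
    }
  )
}

#' Tokenize a read identifier into numeric and text fields
#'
#' Maximal runs of ASCII digits become `NUM` fields (value plus original
#' width, so leading zeros survive); maximal runs of non-digits become `TEXT`
#' fields.  Re-joining the fields in order reproduces the identifier
#' byte-exactly.  Digit runs longer than 15 characters are kept as `TEXT`
#' (they exceed exact double-precision integer range).
#'
#' @param identifier A single identifier string (no newline bytes).
#' @return A `data.frame` with columns `tag` (`"NUM"`/`"TEXT"`), `text`
#'   (original bytes of the field), `value` (numeric, `NA` for text) and
#'   `width`.
#' @examples
#' tokenize_identifier("SRR554369.1 1/1")
#' @export
tokenize_identifier <- function(identifier) {
  stopifnot(is.character(identifier), length(identifier) == 1L)
  if (nchar(identifier) == 0L) {
    return(data.frame(tag = character(), text = character(),
                      value = numeric(), width = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("[0-9]+|[^0-9]+", identifier, perl = TRUE)[[1L]]
  toks <- regmatches(identifier, list(m))[[1L]]
  is_num <- grepl("^[0-9]+$", toks) & nchar(toks) <= 15L
  data.frame(
    tag = ifelse(is_num, "NUM", "TEXT"),
    text = toks,
    value = ifelse(is_num, suppressWarnings(as.numeric(toks)), NA_real_),
    width = nchar(toks),
    stringsAsFactors = FALSE
  )
}

#' Rebuild an identifier from its tokenization
#'
#' Inverse of [tokenize_identifier()]; zero-padded numeric fields are
#' restored from their recorded widths.
#'
#' @param tokens A tokenization data frame.
#' @return The identifier string.
#' @export
detokenize_identifier <- function(tokens) {
  if (nrow(tokens) == 0L) return("")
  parts <- ifelse(tokens$tag == "NUM",
                  pad_num(tokens$value, tokens$width),
                  tokens$text)
  paste(parts, collapse = "")
}

same_template <- function(prev, cur) {
  nrow(prev) == nrow(cur) && all(prev$tag == cur$tag)
}

#' Delta-encode the numeric fields of consecutive identifier tokenizations
#'
#' For two tokenizations sharing a template (same field count and tags),
#' numeric fields are reduced to residuals `current - previous` and text
#' fields to a same/changed flag plus the literal when changed.  The first
#' record of a block is delta-coded against an all-zeros/empty predecessor.
#'
#' @param prev,cur Tokenization data frames with identical templates.
#' @return A list with `num_residuals`, `num_widths`, `text_changed`,
#'   `text_literals` (literals for the changed text fields, in order).
#' @export
delta_encode_numeric <- function(prev, cur) {
  if (!same_template(prev, cur)) stop("template mismatch: record must be stored literally")
  is_num <- cur$tag == "NUM"
  lit <- cur$text[!is_num & cur$text != prev$text]
  list(
    num_residuals = cur$value[is_num] - prev$value[is_num],
    num_widths = cur$width[is_num],
    text_changed = cur$text[!is_num] != prev$text[!is_num],
    text_literals = lit
  )
}

#' @rdname delta_encode_numeric
#' @param residuals A residual list from [delta_encode_numeric()].
#' @return For `delta_apply_numeric()`: the reconstructed tokenization.
#' @export
delta_apply_numeric <- function(prev, residuals) {
  cur <- prev
  is_num <- prev$tag == "NUM"
  cur$value[is_num] <- prev$value[is_num] + residuals$num_residuals
  cur$width[is_num] <- residuals$num_widths
  cur$text[is_num] <- pad_num(cur$value[is_num], cur$width[is_num])
  idx_text <- which(!is_num)
  j <- 1L
  for (i in seq_along(idx_text)) {
    if (residuals$text_changed[i]) {
      cur$text[idx_text[i]] <- residuals$text_literals[j]
      j <- j + 1L
    }
  }
  cur$width[idx_text] <- nchar(cur$text[idx_text])
  cur
}

# decimal rendering of a non-negative integer-valued double, zero-padded to
# width w; formatC is avoided (it refuses to zero-pad the value 0)
num_to_str <- function(v) sprintf("%.0f", v)

pad_num <- function(v, w) {
  s <- num_to_str(v)
  pad <- w - nchar(s)
  ifelse(pad > 0, paste0(strrep("0", pmax(pad, 0)), s), s)
}

zero_template <- function(tokens) {
  z <- tokens
  is_num <- z$tag == "NUM"
  z$value[is_num] <- 0
  z$text[is_num] <- "0"
  z$width[is_num] <- 1L
  z$text[!is_num] <- ""
  z$width[!is_num] <- 0L
  z
}

natural_width <- function(value) nchar(num_to_str(value))

#' Compress an identifier stream
#'
#' Pipeline: tokenization with [tokenize_identifier()], per-field delta
#' coding against the previous record (template changes re-baseline against
#' an all-zeros predecessor; pathological records fall back to raw literals),
#' then two byte streams — structural/residual bytes (flags, zig-zag varint
#' residuals, widths) and text bytes — each compressed with a single
#' order-2 finite-context model over bytes and the shared range coder.
#'
#' @param identifiers Character vector of identifiers.
#' @return A raw payload; [decode_identifiers()] inverts it exactly.
#' @export
encode_identifiers <- function(identifiers) {
  struct <- new_bytebuf()
  textb <- new_bytebuf()
  prev <- NULL
  for (id in identifiers) {
    toks <- tokenize_identifier(id)
    literal <- nrow(toks) > 0L && any(toks$width > 255L & toks$tag == "NUM")
    if (literal) {
      struct$add(as.raw(1L))
      idb <- charToRaw(id)
      struct$add(varint_bytes(length(idb)))
      textb$add(idb)
      prev <- NULL
      next
    }
    is_num <- toks$tag == "NUM"
    if (is.null(prev) || !same_template(prev, toks)) {
      struct$add(as.raw(2L))
      struct$add(varint_bytes(nrow(toks)))
      if (nrow(toks)) struct$add(as.raw(ifelse(is_num, 0L, 1L)))
      base <- zero_template(toks)
      explicit_text <- TRUE
    } else {
      base <- prev
      changed <- toks$text[!is_num] != base$text[!is_num]
      if (sum(!is_num) <= 6L) {
        # record flag type 0: text-changed flags packed into the high bits
        struct$add(as.raw(0L + 4L * sum(2^(which(changed) - 1L))))
        explicit_text <- FALSE
      } else {
        struct$add(as.raw(3L))  # explicit per-field text flags follow inline
        explicit_text <- TRUE
      }
    }
    for (i in seq_len(nrow(toks))) {
      if (is_num[i]) {
        struct$add(varint_bytes(zigzag(toks$value[i] - base$value[i])))
        w <- if (toks$width[i] == natural_width(toks$value[i])) 0L else toks$width[i]
        struct$add(as.raw(w))
      } else {
        field_changed <- toks$text[i] != base$text[i]
        if (explicit_text) struct$add(as.raw(as.integer(field_changed)))
        if (field_changed) {
          fb <- charToRaw(toks$text[i])
          struct$add(varint_bytes(length(fb)))
          textb$add(fb)
        }
      }
    }
    prev <- toks
  }
  sb <- struct$bytes()
  tb <- textb$bytes()
  es <- fcm_bytes_encode_(sb, 2L)
  et <- fcm_bytes_encode_(tb, 2L)
  c(u32_to_raw(length(sb)), u32_to_raw(length(tb)), u32_to_raw(length(es)),
    es, et)
}

#' Decompress an identifier stream
#'
#' @param payload Raw payload from [encode_identifiers()].
#' @param n Number of identifiers to decode.
#' @return Character vector of identifiers.
#' @export
decode_identifiers <- function(payload, n) {
  if (length(payload) < 12L) stop("identifier payload corrupt: header too short")
  n_struct <- raw_to_u32(payload[1:4])
  n_text <- raw_to_u32(payload[5:8])
  len_es <- raw_to_u32(payload[9:12])
  if (12L + len_es > length(payload)) stop("identifier payload corrupt: truncated")
  es <- payload[seq_len(len_es) + 12L]
  et <- payload[-seq_len(len_es + 12L)]
  sb <- fcm_bytes_decode_(es, n_struct, 2L)
  tb <- fcm_bytes_decode_(et, n_text, 2L)
  sr <- new_bytereader(sb)
  tr <- new_bytereader(tb)
  out <- character(n)
  prev <- NULL
  for (r in seq_len(n)) {
    flag_byte <- sr$byte()
    flag <- flag_byte %% 4L
    mask <- flag_byte %/% 4L
    if (flag == 1L) {
      len <- sr$varint()
      out[r] <- rawToChar(tr$take(len))
      prev <- NULL
      next
    }
    explicit_text <- TRUE
    if (flag == 2L) {
      ntok <- sr$varint()
      tags <- if (ntok > 0) {
        ifelse(vapply(seq_len(ntok), function(i) sr$byte(), integer(1)) == 0L,
               "NUM", "TEXT")
      } else character()
      toks <- data.frame(tag = tags, text = rep("", ntok),
                         value = rep(NA_real_, ntok),
                         width = rep(0L, ntok), stringsAsFactors = FALSE)
      base <- zero_template(toks)
      toks <- base
    } else {
      if (is.null(prev)) stop("payload corrupt: delta before template")
      toks <- prev
      base <- prev
      if (flag == 0L) explicit_text <- FALSE
    }
    text_i <- 0L
    for (i in seq_len(nrow(toks))) {
      if (toks$tag[i] == "NUM") {
        delta <- unzigzag(sr$varint())
        toks$value[i] <- base$value[i] + delta
        w <- sr$byte()
        toks$width[i] <- if (w == 0L) natural_width(toks$value[i]) else w
        toks$text[i] <- pad_num(toks$value[i], toks$width[i])
      } else {
        text_i <- text_i + 1L
        ch <- if (explicit_text) {
          sr$byte()
        } else {
          (mask %/% 2^(text_i - 1L)) %% 2L
        }
        if (ch == 1L) {
          len <- sr$varint()
          toks$text[i] <- rawToChar(tr$take(len))
        } else {
          toks$text[i] <- base$text[i]
        }
        toks$width[i] <- nchar(toks$text[i])
      }
    }
    out[r] <- paste(toks$text, collapse = "")
    prev <- toks
  }
  out
}
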