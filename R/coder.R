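#' Range-code a symbol sequence under a fixed distribution
#'
#' Multi-symbol interface to the shared adaptive range coder, with a static
#' (non-adaptive) probability model given as integer frequencies.  The coder
#' is integer-only (32-bit range register, 16-bit probability resolution,
#' byte-wise renormalization), so payloads are identical across platforms,
#' and code length stays within a small constant of the model entropy
#' `-sum(log2(p_i))`.
#'
#' @param symbols Integer vector of 1-based symbol indices.
#' @param freqs Integer frequencies per symbol; `sum(freqs)` must be in
#'   `[1, 65536]`.  A symbol with zero frequency cannot be coded and raises
#'   an error naming the position and symbol.
#' @return A raw payload.  An empty input yields the fixed-size flush-only
#'   payload (4 bytes).
#' @seealso [rc_decode()] for the inverse, [rc_encode_adaptive()] for an
#'   adaptive order-0 model.
#' @export
rc_encode <- function(symbols, freqs) {
  rc_encode_static_(as.integer(symbols), as.integer(freqs))
}

#' Decode a range-coded payload under a fixed distribution
#'
#' Inverse of [rc_encode()]: `rc_decode(rc_encode(s, f), f, length(s))`
#' reproduces `s` exactly.  A truncated or corrupted payload raises an error
#' rather than returning wrong symbols (the decoder checks that the payload
#' is consumed exactly).
#'
#' @param payload Raw payload from [rc_encode()].
#' @param freqs The same frequencies used to encode.
#' @param n Number of symbols to decode.
#' @return Integer vector of 1-based symbol indices.
#' @export
rc_decode <- function(payload, freqs, n) {
  rc_decode_static_(payload, as.integer(freqs), as.integer(n))
}

#' Range-code a bit sequence with a fixed bit probability
#'
#' Binary interface to the shared range coder, used natively by the
#' context-mixing quality codec.
#'
#' @param bits Integer/logical vector of bits.
#' @param p1 Probability that a bit is 1, as an integer in `[1, 65535]`
#'   out of 65536 (probabilities are clamped away from 0 and 1 so no symbol
#'   ever has zero probability).
#' @return A raw payload.
#' @export
rc_encode_bits <- function(bits, p1) {
  rc_encode_bits_(as.integer(bits), as.integer(p1))
}

#' @rdname rc_encode_bits
#' @param payload Raw payload from [rc_encode_bits()].
#' @param n Number of bits to decode.
#' @export
rc_decode_bits <- function(payload, p1, n) {
  rc_decode_bits_(payload, as.integer(p1), as.integer(n))
}

#' Range-code symbols with an adaptive order-0 model
#'
#' Encoder and decoder maintain bit-identical model state (counts updated
#' after each symbol with the same schedule), demonstrating the
#' encoder/decoder symmetry contract that all the package's codecs rely on.
#'
#' @param symbols Integer vector of 1-based symbol indices in `1..nsym`.
#' @param nsym Alphabet size.
#' @return A raw payload.
#' @export
rc_encode_adaptive <- function(symbols, nsym) {
  rc_encode_adaptive_(as.integer(symbols), as.integer(nsym))
}

#' @rdname rc_encode_adaptive
#' @param payload Raw payload from [rc_encode_adaptive()].
#' @param n Number of symbols to decode.
#' @export
rc_decode_adaptive <- function(payload, nsym, n) {
  rc_decode_adaptive_(payload, as.integer(nsym), as.integer(n))
}

#' 64-bit FNV-1a checksum of a raw vector
#'
#' Non-cryptographic stream checksum used by the archive container to detect
#' corruption; returned as 8 raw bytes (little-endian).
#'
#' @param data A raw vector.
#' @return A length-8 raw vector.
#' @export
fq_checksum <- function(data) {
  fnv1a64_(data)
}
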