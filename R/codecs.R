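#' Codec configuration
#'
#' Collects every tunable parameter of the three stream codecs.  The
#' configuration used at compression time is embedded in the archive header,
#' so decompression never depends on package defaults.
#'
#' @param seq_orders Context orders of the competing finite-context models
#'   for the nucleotide stream.  A spread of short and long contexts lets the
#'   competition adapt to both noisy and repetitive sequence.
#' @param seq_alpha Smoothing pseudo-count of the sequence models.
#' @param seq_decay Exponential decay of the per-model code-length
#'   accumulator that drives the competition weights, in (0, 1); 0.95 gives
#'   an effective memory of about 20 symbols.
#' @param seq_hash_bits Hashed-table key width for model orders above 8
#'   (exact tables are used below); bounds memory deterministically.
#' @param qual_predictors Logical mask over the six quality-bit predictors
#'   (order-0 bit tree; previous score q1; (q1, q2); quantized position;
#'   (q1, max of last 8); delta sign).  Used for ablation studies.
#' @param qual_pred_shift Predictor learning rate as a right-shift
#'   (rate = 1/2^shift; default 1/32).
#' @param qual_mix_shift Mixer weight-update shift (default corresponds to
#'   eta = 1/512 in the logistic-mixing update).
#' @param qual_buckets Number of previous-score buckets selecting the mixer
#'   weight set.
#' @param qual_pos_buckets Number of log-spaced read-position buckets
#'   (log spacing keeps long variable-length reads from exploding the
#'   position context).
#' @return A list of class `fq_config`.
#' @export
fq_codec_config <- function(seq_orders = c(2L, 5L, 8L, 11L),
                            seq_alpha = 1 / 16,
                            seq_decay = 0.95,
                            seq_hash_bits = 24L,
                            qual_predictors = rep(TRUE, 6L),
                            qual_pred_shift = 5L,
                            qual_mix_shift = 13L,
                            qual_buckets = 8L,
                            qual_pos_buckets = 16L) {
  stopifnot(length(seq_orders) >= 1, all(seq_orders >= 0),
            seq_alpha > 0, seq_decay > 0, seq_decay < 1,
            seq_hash_bits >= 16, seq_hash_bits <= 26,
            length(qual_predictors) == 6L, any(qual_predictors),
            qual_pred_shift >= 1, qual_mix_shift >= 1,
            qual_buckets >= 1, qual_pos_buckets >= 1)
  structure(list(
    seq_orders = as.integer(seq_orders),
    seq_alpha = seq_alpha,
    seq_decay = seq_decay,
    seq_hash_bits = as.integer(seq_hash_bits),
    qual_predictors = as.logical(qual_predictors),
    qual_pred_shift = as.integer(qual_pred_shift),
    qual_mix_shift = as.integer(qual_mix_shift),
    qual_buckets = as.integer(qual_buckets),
    qual_pos_buckets = as.integer(qual_pos_buckets)
  ), class = "fq_config")
}

#' Compress a nucleotide sequence stream
#'
#' Competing finite-context models of several orders each predict the next
#' base; their predictions are blended with weights derived from each
#' model's recent code length (exponentially decayed), and the blend drives
#' the shared range coder.  Bases outside A/C/G/T (e.g. N) are coded through
#' a per-position binary escape flag plus a literal side-channel, keeping the
#' 4-symbol model tables small.
#'
#' @param sequences Character vector of reads.
#' @param config An [fq_codec_config()].
#' @return A list: `payload` (raw), `bits_per_read` (the coder's own entropy
#'   accounting, in bits) and `total_bits`.
#' @export
encode_sequences <- function(sequences, config = fq_codec_config()) {
  seq_encode_(sequences, config$seq_orders, config$seq_alpha,
              config$seq_decay, config$seq_hash_bits)
}

#' @rdname encode_sequences
#' @param payload Raw payload from `encode_sequences()`.
#' @param lengths Integer vector of per-read lengths (from the lengths
#'   stream).
#' @return For `decode_sequences()`: the character vector of reads.
#' @export
decode_sequences <- function(payload, lengths, config = fq_codec_config()) {
  seq_decode_(payload, as.integer(lengths), config$seq_orders,
              config$seq_alpha, config$seq_decay, config$seq_hash_bits)
}

#' Compress a quality-score stream with context mixing
#'
#' Each quality symbol (ASCII 33-126) is binarized to 7 bits, most
#' significant first.  For every bit, six context models predict the bit
#' from previously decoded history (previous scores, their maximum over the
#' last 8 positions, quantized read position, running delta sign); a
#' logistic mixer selected by a previous-score bucket combines the stretched
#' predictions, and the shared binary range coder codes the bit.  Contexts
#' reset at read boundaries; the learned tables persist across reads.
#'
#' @param qualities Character vector of quality strings.
#' @param config An [fq_codec_config()].
#' @return A list: `payload` (raw), `bits_per_read`, `total_bits`.
#' @export
encode_qualities <- function(qualities, config = fq_codec_config()) {
  qual_encode_(qualities, config$qual_predictors, config$qual_pred_shift,
               config$qual_mix_shift, config$qual_buckets,
               config$qual_pos_buckets)
}

#' @rdname encode_qualities
#' @param payload Raw payload from `encode_qualities()`.
#' @param lengths Integer vector of per-read lengths.
#' @return For `decode_qualities()`: the character vector of quality strings.
#' @export
decode_qualities <- function(payload, lengths, config = fq_codec_config()) {
  qual_decode_(payload, as.integer(lengths), config$qual_predictors,
               config$qual_pred_shift, config$qual_mix_shift,
               config$qual_buckets, config$qual_pos_buckets)
}

#' Logistic link functions of the context mixer
#'
#' `cm_stretch(p) = ln(p / (1 - p))` and its inverse `cm_squash(x)`, as
#' implemented by the codec's fixed-point tables (12-bit probability
#' resolution), so `cm_squash(cm_stretch(p))` equals `p` up to that
#' quantization.  `cm_mix()` is the mixing rule itself:
#' `squash(sum(w * stretch(p)))`.
#'
#' @param p A probability in (0, 1).
#' @param x A real stretch-domain value.
#' @param w Mixer weights.
#' @return A probability (or stretch value for `cm_stretch`).
#' @export
cm_stretch <- function(p) {
  vapply(p, cm_stretch_, numeric(1))
}

#' @rdname cm_stretch
#' @export
cm_squash <- function(x) {
  vapply(x, cm_squash_, numeric(1))
}

#' @rdname cm_stretch
#' @export
cm_mix <- function(p, w) {
  stopifnot(length(p) == length(w))
  cm_squash(sum(w * cm_stretch(p)))
}

#' Compress the per-read length stream
#'
#' Read lengths are delta-coded (zig-zag varints) and the resulting bytes
#' compressed with an order-1 byte finite-context model.  For fixed-length
#' libraries this stream collapses to almost nothing.
#'
#' @param lengths Integer vector of read lengths.
#' @return A raw payload.
#' @export
encode_lengths <- function(lengths) {
  buf <- new_bytebuf()
  prev <- 0
  for (v in lengths) {
    buf$add(varint_bytes(zigzag(v - prev)))
    prev <- v
  }
  b <- buf$bytes()
  c(u32_to_raw(length(b)), fcm_bytes_encode_(b, 1L))
}

#' @rdname encode_lengths
#' @param payload Raw payload from `encode_lengths()`.
#' @param n Number of reads.
#' @return For `decode_lengths()`: the integer vector of lengths.
#' @export
decode_lengths <- function(payload, n) {
  if (length(payload) < 4L) stop("length payload corrupt: header too short")
  nb <- raw_to_u32(payload[1:4])
  b <- fcm_bytes_decode_(payload[-(1:4)], nb, 1L)
  rd <- new_bytereader(b)
  out <- numeric(n)
  prev <- 0
  for (i in seq_len(n)) {
    prev <- prev + unzigzag(rd$varint())
    out[i] <- prev
  }
  if (any(out < 0 | out >= 2^31)) stop("payload corrupt: implausible read length")
  as.integer(out)
}
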