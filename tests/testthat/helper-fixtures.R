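# Fixture builders used across the suite.  random_fastq_text() constructs
# FASTQ bytes from first principles (plain paste of lines), independently of
# reassemble(), so round-trip tests compare against an oracle that shares no
# code with the implementation under test.

random_records <- function(n, seed, plus_mode = "BARE", newline = "\n",
                           var_len = FALSE, n_rate = 0,
                           qual_chars = strsplit(rawToChar(as.raw(33:126)), "")[[1]]) {
  withr::with_seed(seed, {
    lens <- if (var_len) sample(1:300, n, replace = TRUE) else rep(80L, n)
    seqs <- vapply(lens, function(l) {
      s <- sample(c("A", "C", "G", "T"), l, replace = TRUE)
      if (n_rate > 0) s[runif(l) < n_rate] <- "N"
      paste(s, collapse = "")
    }, character(1))
    quals <- vapply(lens, function(l) {
      paste(sample(qual_chars, l, replace = TRUE), collapse = "")
    }, character(1))
    ids <- sprintf("read_%d run=%d", seq_len(n), sample(1:9, n, replace = TRUE))
    plus <- switch(plus_mode,
      BARE = rep("", n),
      MIRROR = ids,
      VERBATIM = c("note", rep("", n - 1))  # mixed, forces verbatim
    )
    list(ids = ids, seqs = seqs, plus = plus, quals = quals, newline = newline)
  })
}

records_to_fastq_bytes <- function(r) {
  lines <- as.vector(rbind(paste0("@", r$ids), r$seqs, paste0("+", r$plus), r$quals))
  charToRaw(paste0(paste(lines, collapse = r$newline), r$newline))
}

random_fastq_bytes <- function(n, seed, ...) {
  records_to_fastq_bytes(random_records(n, seed, ...))
}

# independent brute-force FCM oracle: count occurrences by direct string scan
brute_force_fcm_prob <- function(text, k, context, symbol,
                                 alphabet = c("A", "C", "G", "T"), alpha = 1) {
  chars <- strsplit(text, "")[[1]]
  n_ctx_sym <- 0L
  n_ctx <- 0L
  if (length(chars) > k) {
    for (i in (k + 1):length(chars)) {
      ctx <- if (k == 0) "" else paste(chars[seq(i - k, i - 1)], collapse = "")
      if (identical(ctx, context)) {
        n_ctx <- n_ctx + 1L
        if (chars[i] == symbol) n_ctx_sym <- n_ctx_sym + 1L
      }
    }
  }
  (n_ctx_sym + alpha) / (n_ctx + alpha * length(alphabet))
}

# correlated quality stream at the band-test study conditions
quality_fixture <- function(n_reads, len, stay_prob, seed) {
  fx <- fq_generate(fq_generator_config(
    n_reads = n_reads, read_length = len, stay_prob = stay_prob, seed = seed))
  decouple(parse_fastq(fx))$qualities
}
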