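# Competing-FCM nucleotide codec: exact inversion, near-entropy behaviour on
# structured vs random sequence, and the competition/learning properties.

test_that("sequence codec inverts exactly, including N and variable lengths", {
  e <- encode_sequences("ACGTN")
  expect_identical(decode_sequences(e$payload, 5L), "ACGTN")

  set.seed(30)
  for (rep in 1:5) {
    lens <- sample(0:200, 50, replace = TRUE)
    seqs <- vapply(lens, function(l) {
      s <- sample(c("A", "C", "G", "T"), l, replace = TRUE)
      s[runif(l) < 0.02] <- "N"
      if (l > 3 && runif(1) < 0.2) s[2] <- "x"  # arbitrary printable literal
      paste(s, collapse = "")
    }, character(1))
    e <- encode_sequences(seqs)
    expect_identical(decode_sequences(e$payload, nchar(seqs)), seqs)
  }
})

test_that("a periodic sequence codes far below 2 bits/base", {
  per <- paste(rep("ACGT", 2500), collapse = "")
  e <- encode_sequences(per)
  # 10,000 bases: 2-bit packing would be 2,500 bytes; demand < 2% of that
  expect_lt(length(e$payload), 0.02 * 2500)
  expect_identical(decode_sequences(e$payload, nchar(per)), per)
})

test_that("iid uniform sequence stays within 5% of 2 bits/base", {
  set.seed(31)
  iid <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
  e <- encode_sequences(iid)
  expect_lte(length(e$payload), 1.05 * 2500)
})

test_that("model-state carry-over makes a repeated read strictly cheaper", {
  set.seed(32)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  e <- encode_sequences(c(s, s))
  expect_lt(e$bits_per_read[2], e$bits_per_read[1])
})

test_that("the blend never does worse than the worst single model", {
  set.seed(33)
  fixtures <- list(
    periodic = paste(rep("ACGTTGCA", 500), collapse = ""),
    iid = paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = ""),
    motif = paste(rep(paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                            collapse = ""), 40), collapse = "")
  )
  for (s in fixtures) {
    blended <- encode_sequences(s)$total_bits
    singles <- vapply(c(2L, 5L, 8L, 11L), function(k) {
      encode_sequences(s, fq_codec_config(seq_orders = k))$total_bits
    }, numeric(1))
    expect_lte(blended, max(singles) + 1e-6)
  }
})

test_that("the coder's entropy accounting matches the payload size", {
  set.seed(34)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  e <- encode_sequences(s)
  expect_lte(8 * length(e$payload), e$total_bits + 64)
  expect_gte(8 * length(e$payload), e$total_bits - 8)
})

test_that("length stream delta codec inverts on fixed and variable lengths", {
  for (lens in list(rep(100L, 500), sample(50:5000, 300, replace = TRUE),
                    integer(), 0L)) {
    p <- encode_lengths(lens)
    expect_identical(decode_lengths(p, length(lens)), as.integer(lens))
  }
  # fixed-length libraries collapse to almost nothing
  expect_lt(length(encode_lengths(rep(100L, 10000))), 60)
})
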