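test_that("parse_fastq reads minimal records and strips markers", {
  rec <- parse_fastq(charToRaw("@r1\nACGT\n+\nIIII\n"))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$identifier, "r1")
  expect_equal(rec$sequence, "ACGT")
  expect_equal(rec$plus, "")
  expect_equal(rec$quality, "IIII")
  expect_equal(attr(rec, "newline_style"), "LF")

  rec2 <- parse_fastq(charToRaw("@r1\nACGT\n+r1\nIIII\n@r2\nNNNN\n+r2\n!!!!\n"))
  expect_equal(nrow(rec2), 2L)
  expect_equal(rec2$plus, c("r1", "r2"))

  expect_equal(nrow(parse_fastq(raw())), 0L)
})

test_that("parse_fastq rejects malformed input with located diagnostics", {
  expect_error(parse_fastq(charToRaw("@r1\nACGT\n+\nIII\n")),
               "quality length 3 != sequence length 4 at record 0")
  # truncated trailing record: byte offset of the leftover lines is named
  expect_error(parse_fastq(charToRaw("@r1\nACGT\n+\nIIII\n@r2\nAC\n")),
               "truncated trailing record.*offset 16")
  expect_error(parse_fastq(charToRaw("@r1\nACGT\n+\nIIII")),
               "no final newline")
  expect_error(parse_fastq(charToRaw("@r1\r\nACGT\nIIII\n+\n")),
               "mixed newline")
  # wrapped (multi-line) FASTQ is not 4-line FASTQ
  expect_error(parse_fastq(charToRaw("@r1\nAC\nGT\n+\nIIII\n@r2\nAC\n+\n")),
               "wrapped FASTQ")
  expect_error(parse_fastq(charToRaw("@\nAC\n+\nII\n")), "empty identifier")
})

test_that("plus-line classification covers the three modes", {
  bare <- parse_fastq(charToRaw("@a\nAC\n+\nII\n@b\nGG\n+\nJJ\n"))
  expect_equal(classify_plus_lines(bare), "BARE")

  mirror <- parse_fastq(charToRaw(
    "@SRR554369.1\nAC\n+SRR554369.1\nII\n@SRR554369.2\nGG\n+SRR554369.2\nJJ\n"))
  expect_equal(classify_plus_lines(mirror), "MIRROR")

  mixed <- parse_fastq(charToRaw("@a\nAC\n+\nII\n@b\nGG\n+note\nJJ\n"))
  expect_equal(classify_plus_lines(mixed), "VERBATIM")

  # order-insensitivity for BARE/VERBATIM detection
  expect_equal(classify_plus_lines(mixed[2:1, ]), "VERBATIM")
})

test_that("decouple produces conforming bundles, including degenerate ones", {
  rec <- parse_fastq(charToRaw("@a\nAC\n+\nII\n@b\nGG\n+\nJJ\n"))
  b <- decouple(rec)
  expect_s3_class(b, "fq_bundle")
  expect_equal(b$record_count, 2L)
  expect_equal(b$plus_mode, "BARE")
  expect_length(b$plus_payload, 0L)

  b0 <- decouple(parse_fastq(raw()))
  expect_equal(b0$record_count, 0L)
  expect_equal(b0$plus_mode, "BARE")
  expect_identical(reassemble(b0), raw())

  mirror <- parse_fastq(charToRaw("@a\nAC\n+a\nII\n"))
  bm <- decouple(mirror)
  expect_equal(bm$plus_mode, "MIRROR")
  expect_length(bm$plus_payload, 0L)
})

test_that("reassemble inverts parse+decouple byte-exactly on randomized inputs", {
  expect_identical(
    reassemble(structure(list(identifiers = "r1", sequences = "ACGT",
                              plus_mode = "BARE", plus_payload = character(),
                              qualities = "IIII", record_count = 1L,
                              newline_style = "LF"), class = "fq_bundle")),
    charToRaw("@r1\nACGT\n+\nIIII\n"))

  cases <- expand.grid(plus = c("BARE", "MIRROR", "VERBATIM"),
                       nl = c("\n", "\r\n"), var = c(FALSE, TRUE),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    x <- random_fastq_bytes(40, seed = 1000 + i, plus_mode = cases$plus[i],
                            newline = cases$nl[i], var_len = cases$var[i])
    rec <- parse_fastq(x)
    expect_identical(reassemble(decouple(rec)), x)
    # decouple(parse(reassemble(b))) is b again
    b <- decouple(rec)
    b2 <- decouple(parse_fastq(reassemble(b)))
    expect_identical(unclass(b2), unclass(b))
  }

  # heavier single case: 1000 randomized records
  x <- random_fastq_bytes(1000, seed = 7, plus_mode = "VERBATIM", var_len = TRUE)
  expect_identical(reassemble(decouple(parse_fastq(x))), x)
})

test_that("stream byte lengths plus per-record overhead account for the file size", {
  for (nl in c("\n", "\r\n")) {
    x <- random_fastq_bytes(25, seed = 5, plus_mode = "MIRROR", newline = nl)
    b <- decouple(parse_fastq(x))
    n <- b$record_count
    nlw <- nchar(nl)
    plus_bytes <- switch(b$plus_mode,
      BARE = 0L,
      MIRROR = sum(nchar(b$identifiers)),
      VERBATIM = sum(nchar(b$plus_payload)))
    expected <- sum(nchar(b$identifiers)) + sum(nchar(b$sequences)) +
      sum(nchar(b$qualities)) + plus_bytes +
      n * (2L + 4L * nlw)  # '@' + '+' markers and four newlines per record
    expect_identical(length(x), as.integer(expected))
  }
})
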