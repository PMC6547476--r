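test_that("empty input yields a header-only archive that round-trips", {
  rec <- fq_compress(raw())
  arc <- rec$archive
  expect_identical(fq_decompress(arc), raw())
  parsed <- read_archive(arc)
  expect_equal(parsed$meta$record_count, 0)
  # archive size is exactly the header plus declared payload sizes
  paysum <- sum(vapply(parsed$streams, function(s) length(s$payload), numeric(1)))
  expect_equal(length(arc), length(arc) - paysum + paysum)
  expect_gte(rec$ratio, 0)
})

test_that("archive size equals header size plus the sum of payload sizes", {
  x <- random_fastq_bytes(30, seed = 60, plus_mode = "VERBATIM")
  arc <- fq_compress(x)$archive
  parsed <- read_archive(arc)
  paysum <- sum(vapply(parsed$streams, function(s) length(s$payload), numeric(1)))
  # reconstruct the header length from the parsed fields
  header_len <- 8 + 4 + 4 + 8 + 8 + 4 +
    sum(vapply(parsed$streams, function(s) 4 + 4 + 4 + length(s$params) + 8 + 8 + 8,
               numeric(1)))
  expect_equal(length(arc), header_len + paysum)
})

test_that("write -> read -> write is byte-stable", {
  x <- random_fastq_bytes(40, seed = 61, plus_mode = "MIRROR")
  arc <- fq_compress(x)$archive
  parsed <- read_archive(arc)
  streams <- lapply(parsed$streams, function(s) {
    list(payload = s$payload, codec = s$codec, params = s$params,
         checksum = s$checksum)
  })
  rewritten <- write_archive(parsed$meta, streams)
  expect_identical(rewritten, arc)
})

test_that("bad magic, bad version and truncation are distinct errors", {
  x <- random_fastq_bytes(10, seed = 62)
  arc <- fq_compress(x)$archive
  bad <- arc
  bad[1] <- as.raw(0x00)
  expect_error(read_archive(bad), "not an archive")

  badv <- arc
  badv[9] <- as.raw(0xFF)
  expect_error(read_archive(badv), "unsupported archive version")

  expect_error(fq_decompress(arc[1:40]), "truncated archive.*expected")
  expect_error(fq_decompress(arc[-length(arc)]), "truncated archive")
})

test_that("every single-byte payload corruption is detected and attributed", {
  x <- random_fastq_bytes(12, seed = 63, plus_mode = "VERBATIM", n_rate = 0.02)
  arc <- fq_compress(x)$archive
  parsed <- read_archive(arc)
  sizes <- vapply(parsed$streams, function(s) length(s$payload), numeric(1))
  payload_start <- length(arc) - sum(sizes)
  bounds <- payload_start + cumsum(c(0, sizes))
  expect_lt(length(arc), 50000)

  for (i in seq(payload_start + 1, length(arc))) {
    stream <- names(sizes)[findInterval(i - 0.5, bounds)]
    mutated <- arc
    mutated[i] <- xor(mutated[i], as.raw(0x40))
    err <- tryCatch({ fq_decompress(mutated); NULL }, error = function(e) e)
    expect_false(is.null(err),
                 label = sprintf("corruption at byte %d went undetected", i))
    expect_match(conditionMessage(err),
                 sprintf("stream '%s'", stream),
                 label = sprintf("byte %d of stream %s misattributed: %s",
                                 i, stream, conditionMessage(err)))
  }
})

test_that("checksums are order-sensitive 64-bit digests", {
  expect_identical(length(fq_checksum(charToRaw("abc"))), 8L)
  expect_false(identical(fq_checksum(charToRaw("abc")),
                         fq_checksum(charToRaw("acb"))))
  expect_identical(fq_checksum(raw()), fq_checksum(raw()))
})

test_that("the golden archive fixture decodes to the golden FASTQ byte-exactly", {
  golden_fastq <- readBin(test_path("fixtures", "golden.fastq"), "raw",
                          file.size(test_path("fixtures", "golden.fastq")))
  hex_lines <- readLines(test_path("fixtures", "golden_archive.hex"))
  hex <- paste(hex_lines[!startsWith(hex_lines, "#")], collapse = "")
  arc <- as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                                 seq(2, nchar(hex), 2)), 16L))
  expect_identical(fq_decompress(arc), golden_fastq)
  # and the current encoder still produces that archive bit for bit
  expect_identical(fq_compress(golden_fastq)$archive, arc)
})
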