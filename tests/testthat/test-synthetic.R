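test_that("generator produces the requested structure deterministically", {
  cfg <- fq_generator_config(n_reads = 3, read_length = 4, n_rate = 0,
                             id_template = "r{i}", plus_mode = "BARE", seed = 7)
  fx <- fq_generate(cfg)
  rec <- parse_fastq(fx)
  expect_equal(nrow(rec), 3L)
  expect_equal(nchar(rec$sequence), rep(4L, 3))
  expect_equal(rec$identifier, c("r1", "r2", "r3"))
  expect_true(all(rec$plus == ""))

  expect_identical(fq_generate(cfg), fx)
  expect_false(identical(fq_generate(fq_generator_config(
    n_reads = 3, read_length = 4, id_template = "r{i}", seed = 8)), fx))

  # the generator restores the caller's RNG state
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(fq_generate(cfg))
  expect_identical(rnorm(1), before)
})

test_that("invalid generator configs name the offending fields", {
  expect_error(fq_generator_config(n_rate = 1.5, stay_prob = 0),
               "invalid generator config field\\(s\\): n_rate, stay_prob")
  expect_error(fq_generator_config(phred_range = c(10, 5)), "phred_range")
})

test_that("quality scores carry strong short-range correlation", {
  fx <- fq_generate(fq_generator_config(n_reads = 1000, read_length = 100,
                                        stay_prob = 0.9, seed = 5))
  quals <- decouple(parse_fastq(fx))$qualities
  q <- utf8ToInt(paste(quals, collapse = "")) - 33L
  # lag-1 autocorrelation within reads (drop cross-read pairs)
  keep <- rep(c(rep(TRUE, 99), FALSE), length(quals))
  x <- q[-length(q)][keep[-length(q)]]
  y <- q[-1][keep[-length(q)]]
  expect_gt(cor(x, y), 0.5)
})

test_that("lag-1 autocorrelation increases with the stay-probability", {
  ac <- vapply(c(0.5, 0.9), function(s) {
    fx <- fq_generate(fq_generator_config(n_reads = 400, read_length = 100,
                                          stay_prob = s, seed = 9))
    q <- utf8ToInt(paste(decouple(parse_fastq(fx))$qualities, collapse = "")) - 33L
    cor(q[-1], q[-length(q)])
  }, numeric(1))
  expect_gt(ac[2], ac[1])
})

test_that("fixture matrix spans the benchmark characteristics", {
  fm <- fq_fixture_matrix(n_reads = 60)
  nondegen <- setdiff(names(fm), c("empty", "single_record", "constant_quality"))
  expect_gte(length(nondegen), 12L)

  for (nm in names(fm)) {
    rec <- parse_fastq(fm[[nm]])  # must parse with zero errors
    expect_true(is.data.frame(rec), label = nm)
  }
  expect_identical(fm$empty, raw())
  expect_equal(nrow(parse_fastq(fm$single_record)), 1L)

  cq <- parse_fastq(fm$constant_quality)
  expect_true(all(vapply(cq$quality, function(q) {
    all(strsplit(q, "")[[1]] == "I")
  }, logical(1))))

  pb <- parse_fastq(fm$pacbio_bare_N0)
  expect_gte(length(unique(nchar(pb$sequence))), 3L)
  il <- parse_fastq(fm$illumina_bare_N0)
  expect_equal(length(unique(nchar(il$sequence))), 1L)

  # N-rate fixtures actually contain N
  expect_true(grepl("N", paste(parse_fastq(fm$illumina_bare_N0.01)$sequence,
                               collapse = ""), fixed = TRUE))
  # plus modes are as labelled
  expect_equal(classify_plus_lines(parse_fastq(fm$illumina_mirror_N0)), "MIRROR")
  expect_equal(classify_plus_lines(parse_fastq(fm$illumina_verbatim_N0)), "VERBATIM")
})
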