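# Context-mixing quality codec: logistic link correctness, exact inversion
# across the fixture classes, and the learning/mixing properties that make
# correlated quality streams compressible.

test_that("stretch and squash are inverse logistic links", {
  expect_equal(cm_squash(0), 0.5, tolerance = 1e-3)
  expect_equal(cm_stretch(0.5), 0, tolerance = 1e-2)
  expect_equal(cm_stretch(0.9), log(9), tolerance = 0.02)
  expect_equal(cm_squash(log(9)), 0.9, tolerance = 1e-3)
  for (p in c(0.05, 0.2, 0.37, 0.5, 0.73, 0.99)) {
    expect_equal(cm_squash(cm_stretch(p)), p, tolerance = 1 / 256)
  }
  expect_error(cm_stretch(0), "\\(0, 1\\)")
  expect_error(cm_stretch(1.2), "\\(0, 1\\)")
})

test_that("mixing rule reduces to the predictors in the canonical cases", {
  # all predictors indifferent -> indifferent, whatever the weights
  expect_equal(cm_mix(c(0.5, 0.5), c(0.3, 1.7)), 0.5, tolerance = 1e-3)
  # single active predictor with unit weight -> that predictor
  expect_equal(cm_mix(c(0.9, 0.5), c(1, 0)), 0.9, tolerance = 1e-3)
  # agreeing predictors with weights summing to one -> the shared prediction
  expect_equal(cm_mix(c(0.8, 0.8), c(0.5, 0.5)), 0.8, tolerance = 1e-3)
})

test_that("quality codec inverts exactly across the fixture classes", {
  cases <- list(
    constant = strrep("I", 2000),
    adversarial = {
      set.seed(50)
      paste(sample(strsplit(rawToChar(as.raw(33:126)), "")[[1]], 3000,
                   replace = TRUE), collapse = "")
    }
  )
  for (q in cases) {
    e <- encode_qualities(q)
    expect_identical(decode_qualities(e$payload, nchar(q)), q)
  }

  # Illumina-like and PacBio-like multi-read streams
  for (seed in 0:9) {
    quals <- if (seed %% 2 == 0) {
      quality_fixture(100, 100, 0.9, seed)
    } else {
      q <- decouple(parse_fastq(fq_generate(fq_generator_config(
        platform = "PACBIO_LIKE", n_reads = 60, phred_range = c(0L, 30L),
        stay_prob = 0.8, seed = seed))))$qualities
      q
    }
    e <- encode_qualities(quals)
    expect_identical(decode_qualities(e$payload, nchar(quals)), quals)
  }

  expect_identical(decode_qualities(encode_qualities(character())$payload,
                                    integer()), character())
})

test_that("quality symbols outside ASCII 33-126 are rejected with location", {
  expect_error(encode_qualities(c("III", "II ")),
               "record 2 position 3")
})

test_that("constant quality codes to well under 1% of raw", {
  e <- encode_qualities(strrep("I", 10000))
  expect_lt(length(e$payload), 100)
})

test_that("iid 4-symbol qualities stay within 10% above 2 bits/symbol", {
  set.seed(51)
  q <- paste(sample(c("!", "5", "I", "~"), 10000, replace = TRUE), collapse = "")
  e <- encode_qualities(q)
  expect_lte(e$total_bits / 10000, 2 * 1.1)
})

test_that("correlation-aware contexts beat the order-0-only configuration", {
  quals <- quality_fixture(100, 100, 0.9, seed = 7)
  full <- encode_qualities(quals)
  order0 <- encode_qualities(quals, fq_codec_config(
    qual_predictors = c(TRUE, rep(FALSE, 5))))
  expect_lt(full$total_bits, order0$total_bits)
})

test_that("bits/symbol decreases strictly with the Markov stay-probability", {
  bps <- vapply(c(0.5, 0.7, 0.9, 0.99), function(s) {
    quals <- quality_fixture(500, 100, s, seed = 42)
    encode_qualities(quals)$total_bits / sum(nchar(quals))
  }, numeric(1))
  expect_true(all(diff(bps) < 0))
})

test_that("the mixer is no worse than the best single predictor plus margin", {
  quals <- quality_fixture(200, 100, 0.9, seed = 11)
  n <- sum(nchar(quals))
  mixed <- encode_qualities(quals)$total_bits / n
  singles <- vapply(1:6, function(i) {
    mask <- rep(FALSE, 6)
    mask[i] <- TRUE
    encode_qualities(quals, fq_codec_config(qual_predictors = mask))$total_bits / n
  }, numeric(1))
  expect_lte(mixed, min(singles) + 0.05)
})

test_that("the coder's entropy accounting matches the quality payload size", {
  quals <- quality_fixture(50, 100, 0.9, seed = 13)
  e <- encode_qualities(quals)
  expect_lte(8 * length(e$payload), e$total_bits + 64)
  expect_gte(8 * length(e$payload), e$total_bits - 8)
})
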