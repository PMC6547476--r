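# The range coder is the shared seam under every codec: these tests pin its
# contract — exact inversion, determinism, near-entropy code lengths and
# honest failure on corrupt payloads.

test_that("degenerate sources code to (almost) nothing", {
  # zero-entropy source: a symbol with probability ~1
  p <- rc_encode_bits(rep(1L, 100), 65535)
  expect_lte(length(p), 8L)
  expect_identical(rc_decode_bits(p, 65535, 100), rep(1L, 100))

  # empty input: fixed-size flush-only payload
  p0 <- rc_encode(integer(), c(1L, 1L))
  expect_identical(length(p0), 4L)
  expect_identical(rc_decode(p0, c(1L, 1L), 0), integer())
})

test_that("64 uniform 4-ary symbols land within a constant of 16 bytes", {
  set.seed(101)
  s <- sample(1:4, 64, replace = TRUE)
  p <- rc_encode(s, rep(16384L, 4))
  expect_gte(length(p), 16L)
  expect_lte(length(p), 16L + 8L)
  expect_identical(rc_decode(p, rep(16384L, 4), 64), s)
})

test_that("payload stays within n*H + 64 bits for constructed iid sources", {
  n <- 10000L
  # H = 0
  p <- rc_encode_bits(rep(0L, n), 1L)
  expect_lte(8 * length(p), 64)
  # H = 1: fair bits
  set.seed(1)
  b <- sample(0:1, n, replace = TRUE)
  p <- rc_encode_bits(b, 32768L)
  expect_lte(8 * length(p), n * 1 + 64)
  expect_identical(rc_decode_bits(p, 32768L, n), b)
  # H = 2: uniform over 4 symbols
  s <- sample(1:4, n, replace = TRUE)
  p <- rc_encode(s, rep(16384L, 4))
  expect_lte(8 * length(p), n * 2 + 64)
  # H = log2(94): uniform over the printable quality alphabet
  s <- sample(1:94, n, replace = TRUE)
  f <- rep(697L, 94)  # 94 * 697 = 65518, within 16-bit resolution
  p <- rc_encode(s, f)
  expect_lte(8 * length(p), n * log2(94) + 64)
  expect_identical(rc_decode(p, f, n), s)
})

test_that("adaptive order-0 coding round-trips and is deterministic", {
  txt <- utf8ToInt("IIJJII") - 32L
  p <- rc_encode_adaptive(txt, 96)
  expect_identical(rc_decode_adaptive(p, 96, length(txt)), txt)

  for (seed in 0:9) {
    set.seed(seed)
    s <- sample(1:94, 10000, replace = TRUE)
    p <- rc_encode_adaptive(s, 94)
    expect_identical(rc_decode_adaptive(p, 94, length(s)), s)
  }

  set.seed(3)
  s <- sample(1:4, 500, replace = TRUE)
  expect_identical(rc_encode_adaptive(s, 4), rc_encode_adaptive(s, 4))
})

test_that("zero-probability symbols and corrupt payloads are coding errors", {
  expect_error(rc_encode(c(1L, 3L), c(10L, 10L, 0L)),
               "zero-probability symbol 3 at position 2")

  set.seed(2)
  s <- sample(1:4, 2000, replace = TRUE)
  p <- rc_encode(s, rep(16384L, 4))
  expect_error(rc_decode(p[-length(p)], rep(16384L, 4), length(s)),
               "corrupt or truncated")
  # truncating an adaptive payload must error, never return wrong symbols
  pa <- rc_encode_adaptive(s, 4)
  expect_error(rc_decode_adaptive(pa[-length(pa)], 4, length(s)),
               "corrupt or truncated")
})

test_that("byte-level FCM coder inverts exactly on text and binary data", {
  for (order in 0:2) {
    x <- charToRaw(paste(rep("the quick brown fox 0123456789", 40), collapse = " "))
    p <- fcm_bytes_encode_(x, order)
    expect_identical(fcm_bytes_decode_(p, length(x), order), x)
  }
  set.seed(9)
  x <- as.raw(sample(0:255, 5000, replace = TRUE))
  p <- fcm_bytes_encode_(x, 1L)
  expect_identical(fcm_bytes_decode_(p, length(x), 1L), x)
  expect_identical(fcm_bytes_encode_(raw(), 1L), fcm_bytes_encode_(raw(), 1L))
  expect_identical(fcm_bytes_decode_(fcm_bytes_encode_(raw(), 2L), 0, 2L), raw())
})
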