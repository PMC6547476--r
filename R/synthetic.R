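#' Configuration for the synthetic FASTQ generator
#'
#' The generator emulates the two benchmark read classes: Illumina-like
#' fixed-length short reads and PacBio-like variable-length long reads.
#' Sequences are i.i.d. A/C/G/T with occasional re-inserted repeat blocks (a
#' per-file 200-base motif, re-inserted with 1% per-read probability, so the
#' high-order sequence models have genomic-style repetition to exploit) and
#' optional N bases.  Quality strings follow a latent first-order Markov
#' level (stay-probability `stay_prob`, otherwise a +/-1..3 step) with a
#' deterministic positional down-drift of `drift_per_100` Phred units per
#' 100 bases, plus independent per-base discrete Gaussian jitter of standard
#' deviation `jitter_sd` emulating instrument noise; everything is clamped
#' to `phred_range`.  Identifiers follow `id_template` with an incrementing
#' index.
#'
#' @param platform `"ILLUMINA_LIKE"` (fixed `read_length`) or
#'   `"PACBIO_LIKE"` (log-normal lengths, minimum 50).
#' @param n_reads Number of records.
#' @param read_length Fixed read length (Illumina-like).
#' @param length_meanlog,length_sdlog Log-normal parameters of PacBio-like
#'   read lengths.
#' @param n_rate Probability that a base is replaced by `N`, in `[0, 1)`.
#' @param stay_prob Markov stay-probability of the latent quality level.
#' @param drift_per_100 Positional quality down-drift per 100 bases.
#' @param jitter_sd Standard deviation of the per-base quality jitter.
#' @param phred_range Two-element integer vector, inclusive Phred bounds
#'   (offset-33 encoding).
#' @param id_template Identifier template; `{i}` is replaced by the record
#'   index (starting at `id_start`) and `{len}` by the read length.
#' @param id_start First record index.
#' @param plus_mode `"BARE"`, `"MIRROR"` or `"VERBATIM"` (a verbatim comment
#'   distinct from the identifier).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A list of class `fq_generator_config`.
#' @export
fq_generator_config <- function(platform = c("ILLUMINA_LIKE", "PACBIO_LIKE"),
                                n_reads = 1000L,
                                read_length = 100L,
                                length_meanlog = log(1000),
                                length_sdlog = 0.45,
                                n_rate = 0,
                                stay_prob = 0.9,
                                drift_per_100 = 2,
                                jitter_sd = 2,
                                phred_range = c(0L, 40L),
                                id_template = "SRR554369.{i} {i}/1",
                                id_start = 1L,
                                plus_mode = c("BARE", "MIRROR", "VERBATIM"),
                                seed = 1L) {
  platform <- match.arg(platform)
  plus_mode <- match.arg(plus_mode)
  problems <- character()
  if (!is.numeric(n_reads) || n_reads < 0) problems <- c(problems, "n_reads")
  if (!is.numeric(read_length) || read_length < 1) problems <- c(problems, "read_length")
  if (!is.numeric(n_rate) || n_rate < 0 || n_rate >= 1) problems <- c(problems, "n_rate")
  if (!is.numeric(stay_prob) || stay_prob <= 0 || stay_prob >= 1) problems <- c(problems, "stay_prob")
  if (!is.numeric(drift_per_100) || drift_per_100 < 0) problems <- c(problems, "drift_per_100")
  if (!is.numeric(jitter_sd) || jitter_sd < 0) problems <- c(problems, "jitter_sd")
  if (length(phred_range) != 2L || phred_range[1] < 0 || phred_range[2] > 93 ||
      phred_range[1] >= phred_range[2]) problems <- c(problems, "phred_range")
  if (!is.character(id_template) || nchar(id_template) == 0) problems <- c(problems, "id_template")
  if (length(problems)) {
    stop(sprintf("invalid generator config field(s): %s",
                 paste(problems, collapse = ", ")))
  }
  structure(list(
    platform = platform, n_reads = as.integer(n_reads),
    read_length = as.integer(read_length),
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    n_rate = n_rate, stay_prob = stay_prob, drift_per_100 = drift_per_100,
    jitter_sd = jitter_sd, phred_range = as.integer(phred_range),
    id_template = id_template, id_start = as.integer(id_start),
    plus_mode = plus_mode, seed = as.integer(seed)
  ), class = "fq_generator_config")
}

#' Generate a synthetic FASTQ byte stream
#'
#' Seeded and deterministic: the same configuration always produces the same
#' bytes.  See [fq_generator_config()] for the data model.
#'
#' @param config An [fq_generator_config()].
#' @return A raw vector of 4-line FASTQ records (LF newlines).
#' @examples
#' fx <- fq_generate(fq_generator_config(n_reads = 3, read_length = 4, seed = 7))
#' rawToChar(fx)
#' @export
fq_generate <- function(config = fq_generator_config()) {
  stopifnot(inherits(config, "fq_generator_config"))
  n <- config$n_reads
  if (n == 0L) return(raw(0))
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  lengths <- if (config$platform == "ILLUMINA_LIKE") {
    rep(config$read_length, n)
  } else {
    pmax(50L, as.integer(round(stats::rlnorm(n, config$length_meanlog,
                                             config$length_sdlog))))
  }
  motif <- sample(c("A", "C", "G", "T"), 200L, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  lo <- config$phred_range[1]
  hi <- config$phred_range[2]

  seqs <- character(n)
  quals <- character(n)
  for (r in seq_len(n)) {
    len <- lengths[r]
    s <- sample(bases, len, replace = TRUE)
    if (stats::runif(1) < 0.01) {
      # re-insert the per-file motif: genomes are repetitive
      at <- sample.int(max(1L, len), 1L)
      span <- min(len - at + 1L, 200L)
      if (span > 0) s[at:(at + span - 1L)] <- motif[seq_len(span)]
    }
    if (config$n_rate > 0) {
      s[stats::runif(len) < config$n_rate] <- "N"
    }
    seqs[r] <- paste(s, collapse = "")

    # latent level: stays with probability s; otherwise a small +/-1..3 step
    # or (half of the moves) a fresh draw from the upper quality band.  The
    # redraws pin the stationary variance so the observable lag-1
    # autocorrelation tracks s instead of the accumulated walk variance.
    level <- numeric(len)
    band_lo <- lo + 0.5 * (hi - lo)
    lvl <- round(stats::runif(1, band_lo, hi))
    move <- stats::runif(len) >= config$stay_prob
    redraw <- stats::runif(len) < 0.5
    jump <- sample(c(-3:-1, 1:3), len, replace = TRUE)
    fresh <- round(stats::runif(len, band_lo, hi))
    for (t in seq_len(len)) {
      if (t > 1L && move[t]) {
        lvl <- if (redraw[t]) fresh[t] else lvl + jump[t]
      }
      if (lvl > hi) lvl <- hi else if (lvl < lo) lvl <- lo
      level[t] <- lvl
    }
    drift <- config$drift_per_100 * (seq_len(len) - 1L) / 100
    q <- round(level - drift + stats::rnorm(len, 0, config$jitter_sd))
    q <- pmin(hi, pmax(lo, q))
    quals[r] <- intToUtf8(q + 33L)
  }

  idx <- config$id_start + seq_len(n) - 1L
  ids <- gsub("{i}", "%IDX%", config$id_template, fixed = TRUE)
  ids <- gsub("{len}", "%LEN%", ids, fixed = TRUE)
  ids <- rep(ids, n)
  ids <- mapply(function(tpl, i, l) {
    gsub("%LEN%", l, gsub("%IDX%", i, tpl, fixed = TRUE), fixed = TRUE)
  }, ids, idx, lengths, USE.NAMES = FALSE)

  plus <- switch(config$plus_mode,
    BARE = rep("+", n),
    MIRROR = paste0("+", ids),
    VERBATIM = paste0("+note", idx)
  )
  lines <- character(4L * n)
  lines[seq(1L, 4L * n, by = 4L)] <- paste0("@", ids)
  lines[seq(2L, 4L * n, by = 4L)] <- seqs
  lines[seq(3L, 4L * n, by = 4L)] <- plus
  lines[seq(4L, 4L * n, by = 4L)] <- quals
  charToRaw(paste0(paste(lines, collapse = "\n"), "\n"))
}

#' Deterministic fixture suite spanning the benchmark's characteristics
#'
#' Generates a named set of small FASTQ byte streams covering
#' platform x plus-mode x N-rate, plus degenerate cases (empty file, single
#' record, constant quality).  Every non-degenerate fixture parses cleanly
#' and the whole matrix is the round-trip test bed for the full pipeline.
#'
#' @param n_reads Reads per Illumina-like fixture (PacBio-like fixtures use
#'   a quarter of this, their reads being ~10x longer).
#' @return A named list of raw vectors.
#' @export
fq_fixture_matrix <- function(n_reads = 400L) {
  out <- list()
  seed <- 100L
  for (platform in c("ILLUMINA_LIKE", "PACBIO_LIKE")) {
    for (plus_mode in c("BARE", "MIRROR", "VERBATIM")) {
      for (n_rate in c(0, 0.01)) {
        seed <- seed + 1L
        nr <- if (platform == "ILLUMINA_LIKE") n_reads else max(2L, n_reads %/% 4L)
        cfg <- fq_generator_config(
          platform = platform, n_reads = nr, n_rate = n_rate,
          plus_mode = plus_mode,
          id_template = if (platform == "ILLUMINA_LIKE") {
            "SRR554369.{i} {i}/1"
          } else {
            "m151004_000000/{i}/0_{len}"
          },
          phred_range = if (platform == "ILLUMINA_LIKE") c(0L, 40L) else c(0L, 30L),
          stay_prob = if (platform == "ILLUMINA_LIKE") 0.9 else 0.8,
          seed = seed
        )
        nm <- sprintf("%s_%s_N%s",
                      if (platform == "ILLUMINA_LIKE") "illumina" else "pacbio",
                      tolower(plus_mode), format(n_rate))
        out[[nm]] <- fq_generate(cfg)
      }
    }
  }
  out$empty <- raw(0)
  out$single_record <- fq_generate(fq_generator_config(n_reads = 1L, seed = 201L))
  const_cfg <- fq_generator_config(n_reads = 50L, seed = 202L)
  const <- fq_generate(const_cfg)
  recs <- parse_fastq(const)
  recs$quality <- vapply(nchar(recs$sequence),
                         function(l) strrep("I", l), character(1))
  out$constant_quality <- reassemble(decouple(recs))
  out
}
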