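#' Compression ratio
#'
#' The ratio between the size of the original and the compressed files
#' (larger is better), reported to 2 decimals.
#'
#' @param original_bytes,compressed_bytes Sizes in the same unit (bytes or
#'   MB); `compressed_bytes` must be positive.
#' @return The ratio, rounded to 2 decimals.
#' @examples
#' compression_ratio(1000, 250)   # 4.00
#' compression_ratio(228.2, 14.0) # 16.30
#' @export
compression_ratio <- function(original_bytes, compressed_bytes) {
  if (!is.numeric(compressed_bytes) || compressed_bytes <= 0) {
    stop("compressed size must be positive")
  }
  round(original_bytes / compressed_bytes, 2)
}

baseline_codecs <- c(gzip = "gzip", bzip2 = "bzip2", xz = "xz")

#' Benchmark compressors on FASTQ inputs
#'
#' Runs this package's pipeline and/or the general-purpose baselines
#' (deflate/gzip, bzip2, LZMA/xz via R's `memCompress`) on each input and
#' reports one record per tool x dataset: sizes, compression ratio,
#' compression and decompression speed in MB/s, and whether the round trip
#' was byte-exact (always measured, never assumed).  A failing tool yields
#' an `NA` row rather than aborting the report.  Everything runs
#' single-threaded in-process; speeds are wall-clock.
#'
#' @param inputs Character vector of FASTQ paths, or a named list of raw
#'   vectors.
#' @param tools Subset of `c("fqcm", "gzip", "bzip2", "xz")`.
#' @param per_stream If `TRUE`, adds the per-stream breakdown for the
#'   package's pipeline: collective identifier+sequence ratio and quality
#'   ratio, computed from the archive's payload sizes (the lengths stream
#'   counts against the sequence side, the container header against none).
#' @param speed_basis `"input"` (default: input MB per second) or
#'   `"output"` (compressed MB per second, the literal reading).
#' @param config Codec configuration for the package's pipeline.
#' @return A `data.frame` with one row per tool x dataset.
#' @export
fq_bench <- function(inputs, tools = c("fqcm", "gzip", "bzip2", "xz"),
                     per_stream = FALSE,
                     speed_basis = c("input", "output"),
                     config = fq_codec_config()) {
  speed_basis <- match.arg(speed_basis)
  tools <- match.arg(tools, c("fqcm", "gzip", "bzip2", "xz"), several.ok = TRUE)
  if (is.character(inputs)) {
    nms <- if (!is.null(names(inputs))) names(inputs) else basename(inputs)
    inputs <- lapply(inputs, function(p) readBin(p, "raw", n = file.info(p)$size))
    names(inputs) <- nms
  }
  if (is.raw(inputs)) inputs <- list(data = inputs)
  if (is.null(names(inputs))) names(inputs) <- paste0("data", seq_along(inputs))

  rows <- list()
  for (ds in names(inputs)) {
    x <- inputs[[ds]]
    for (tool in tools) {
      rec <- tryCatch(
        bench_one(x, tool, config, speed_basis),
        error = function(e) NULL
      )
      if (is.null(rec)) {
        rec <- data.frame(tool = tool, dataset = ds,
                          input_bytes = length(x), output_bytes = NA_real_,
                          ratio = NA_real_, comp_mb_s = NA_real_,
                          decomp_mb_s = NA_real_, peak_mem_mb = NA_real_,
                          round_trip_exact = NA,
                          idseq_ratio = NA_real_, quality_ratio = NA_real_,
                          stringsAsFactors = FALSE)
      } else {
        rec$dataset <- ds
        if (per_stream && tool == "fqcm") {
          ps <- per_stream_ratios(x, config)
          rec$idseq_ratio <- ps$idseq_ratio
          rec$quality_ratio <- ps$quality_ratio
        } else {
          rec$idseq_ratio <- NA_real_
          rec$quality_ratio <- NA_real_
        }
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("tool", "dataset", "input_bytes", "output_bytes", "ratio",
          "comp_mb_s", "decomp_mb_s", "peak_mem_mb", "round_trip_exact",
          "idseq_ratio", "quality_ratio")]
}

bench_one <- function(x, tool, config, speed_basis) {
  mb <- function(b) b / 2^20
  if (tool == "fqcm") {
    t0 <- proc.time()[["elapsed"]]
    rec <- fq_compress(x, config = config)
    t_comp <- proc.time()[["elapsed"]] - t0
    arch <- rec$archive
    t0 <- proc.time()[["elapsed"]]
    back <- fq_decompress(arch)
    t_dec <- proc.time()[["elapsed"]] - t0
    out_bytes <- length(arch)
    exact <- identical(back, x)
  } else {
    type <- baseline_codecs[[tool]]
    t0 <- proc.time()[["elapsed"]]
    comp <- memCompress(x, type = type)
    t_comp <- proc.time()[["elapsed"]] - t0
    t0 <- proc.time()[["elapsed"]]
    back <- memDecompress(comp, type = type, asChar = FALSE)
    t_dec <- proc.time()[["elapsed"]] - t0
    out_bytes <- length(comp)
    exact <- identical(back, x)
  }
  basis <- if (speed_basis == "input") length(x) else out_bytes
  data.frame(
    tool = tool, dataset = NA_character_,
    input_bytes = length(x), output_bytes = out_bytes,
    ratio = compression_ratio(length(x), out_bytes),
    comp_mb_s = round(mb(basis) / max(t_comp, 1e-9), 2),
    decomp_mb_s = round(mb(basis) / max(t_dec, 1e-9), 2),
    peak_mem_mb = NA_real_,
    round_trip_exact = exact,
    stringsAsFactors = FALSE
  )
}

#' Per-stream compression breakdown
#'
#' Compresses `x` and reports, per the benchmark methodology for FASTA-style
#' tools that do not emit separate streams, the collective
#' identifier+sequence ratio (their raw line bytes over the identifier,
#' sequence and length payloads) and the quality-stream ratio.
#'
#' @param x Raw FASTQ bytes or a path.
#' @param config Codec configuration.
#' @return A list: `idseq_ratio`, `quality_ratio`, `stream_payload_bytes`,
#'   `stream_raw_bytes`, `container_overhead_bytes`.
#' @export
per_stream_ratios <- function(x, config = fq_codec_config()) {
  x <- as_fastq_raw(x)
  rec <- fq_compress(x, config = config)
  pay <- rec$stream_payload_bytes
  rawb <- rec$stream_raw_bytes
  idseq_payload <- pay[["identifiers"]] + pay[["sequences"]] + pay[["lengths"]]
  list(
    idseq_ratio = compression_ratio(rawb[["identifiers"]] + rawb[["sequences"]],
                                    idseq_payload),
    quality_ratio = compression_ratio(rawb[["qualities"]], pay[["qualities"]]),
    stream_payload_bytes = pay,
    stream_raw_bytes = rawb,
    container_overhead_bytes = rec$output_bytes - sum(pay)
  )
}

#' Peak memory of a child process
#'
#' Runs a command as a child process and reports the maximum resident set
#' size over its lifetime in MB, via the kernel's accounting
#' (`wait4`/`getrusage`).  This is the "maximum memory bytes required"
#' benchmarking protocol; it is reported, never asserted, because it is
#' hardware- and allocator-dependent.
#'
#' @param cmd Command to execute.
#' @param args Character vector of arguments.
#' @return A list with `peak_mb` (NA if the command could not be run, with a
#'   warning), `elapsed` seconds and `exit_code`.
#' @export
peak_memory <- function(cmd, args = character()) {
  res <- tryCatch(run_measured_(cmd, as.character(args)),
                  error = function(e) NULL)
  if (is.null(res) || res$exit_code == 127L) {
    warning(sprintf("could not measure '%s': command failed to execute", cmd))
    return(list(peak_mb = NA_real_, elapsed = NA_real_,
                exit_code = if (is.null(res)) NA_integer_ else res$exit_code))
  }
  list(peak_mb = res$max_rss_mb, elapsed = res$elapsed,
       exit_code = res$exit_code)
}
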