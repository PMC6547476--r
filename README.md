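# fqcm — lossless FASTQ compression with finite-context models and context mixing

Raw sequencing reads are archived and shipped as FASTQ, and they are big.
General-purpose compressors treat a FASTQ file as one undifferentiated byte
stream, but each record is four lines with radically different statistics:
a machine-generated identifier, a 4-letter nucleotide sequence, a redundant
plus-line, and a quality string whose scores correlate strongly with their
predecessors.  `fqcm` is a self-contained, strictly lossless compressor for
people who store or move sequencing data: it decouples the records into four
streams and compresses each with the model family that fits it, then packs
everything into one checksummed archive that decompresses to a byte-exact
replica of the input — identifiers, plus-line comments and newline
convention included.

The core machinery:

* **Identifiers** are tokenized into numeric/text fields, delta-coded
  against the previous record (an incrementing `read 1`, `read 2`, ...
  counter becomes a stream of `+1` residuals) and coded with single
  order-2 finite-context models over bytes.
* **Sequences** are coded by *competing* finite-context models
  (orders 2/5/8/11 by default): each order-k model predicts
  `P(base | previous k bases)` with additive smoothing, the predictions are
  blended with weights `w ∝ 2^-(decayed code length)`, and the blend drives
  an arithmetic coder.  Non-ACGT bases go through a binary escape plus a
  literal side-channel.
* **Quality scores** are coded bit-by-bit by a context-mixing model in the
  PAQ/ZPAQ tradition: six context models (previous score, score pair,
  log-quantized position, recent maximum, delta sign, order-0 floor) each
  predict the next bit, and a logistic mixer
  `p = squash(Σ wᵢ · stretch(pᵢ))`, trained online, feeds the coder.
* **All streams** share one integer-only adaptive range coder (32-bit range,
  16-bit probabilities), so payloads are deterministic across platforms and
  sit within a small constant of the model entropy.
* The **archive** records codec parameters and double checksums per stream
  (uncompressed bytes and compressed payload), so any single-byte corruption
  is detected and attributed to the stream it hit.

A seeded synthetic FASTQ generator (Illumina-like fixed-length and
PacBio-like variable-length reads, correlated quality scores) makes the
whole pipeline testable without downloading data, and a benchmark harness
reports compression ratio, speed and peak child-process memory.

## Worked example

```r
library(fqcm)

# 2000 Illumina-like reads, 100 bp, correlated qualities, seeded
fx  <- fq_generate(fq_generator_config(n_reads = 2000, seed = 7))
rec <- fq_compress(fx)
sprintf("input %d bytes -> archive %d bytes, ratio %.2f",
        rec$input_bytes, rec$output_bytes, rec$ratio)
#> "input 451786 bytes -> archive 143647 bytes, ratio 3.15"

round(rec$stream_payload_bytes)
#> identifiers   sequences     lengths   qualities
#>        1504       50123          24       91398

ps <- per_stream_ratios(fx)
sprintf("id+seq ratio %.2f, quality ratio %.2f", ps$idseq_ratio, ps$quality_ratio)
#> "id+seq ratio 4.76, quality ratio 2.21"

fq_bench(list(synthetic = fx), tools = c("fqcm", "gzip", "bzip2", "xz"))[,
  c("tool", "output_bytes", "ratio", "round_trip_exact")]
#>    tool output_bytes ratio round_trip_exact
#> 1  fqcm       143647  3.15             TRUE
#> 2  gzip       207324  2.18             TRUE
#> 3 bzip2       168027  2.69             TRUE
#> 4    xz       179504  2.52             TRUE

isTRUE(fq_verify(fq_compress(fx)$archive, fx))
#> TRUE
```

Reading the numbers: the identifier stream all but vanishes (its counters
are pure structure), sequences cost ~2 bits/base on mostly-random synthetic
DNA, and the quality stream — the hardest of the four — compresses at about
2.2:1, inside the 2:1–4:1 range typical for real quality data.  The whole
file beats every general-purpose baseline, and `round_trip_exact` is an
actual byte comparison.

## Command line

```sh
fqcm=$(Rscript -e 'cat(system.file("cli", "fqcm", package = "fqcm"))')
Rscript $fqcm generate -o reads.fastq --n-reads 1000 --seed 1
Rscript $fqcm compress reads.fastq -o reads.arch
Rscript $fqcm verify reads.arch reads.fastq
Rscript $fqcm decompress reads.arch -o roundtrip.fastq
Rscript $fqcm bench reads.fastq --tools self,deflate,bzip2,lzma --per-stream --csv bench.csv
```

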