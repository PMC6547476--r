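---
title: "Methods: hybrid stream-wise FASTQ compression"
author: "fqcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid stream-wise FASTQ compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqcm)
```

## The problem and the approach

Raw sequencing output in FASTQ form is large, highly structured and has to
survive archival byte-for-byte: read identifiers, the plus-line comment, even
the newline convention are part of the record.  General-purpose compressors
treat the file as one byte stream and miss that the four record fields have
completely different statistics.  `fqcm` therefore decouples each 4-line
record into homogeneous streams and gives each stream the model family that
fits it:

* **identifiers** — machine-generated, mostly-constant text with incrementing
  counters: tokenization into numeric/text fields, per-field delta coding,
  then single finite-context models (FCMs) over the residual bytes;
* **sequences** — a 4-symbol alphabet with both noisy and highly repetitive
  regions: several FCMs of different orders *compete*, their predictions
  blended by recent coding performance, with a binary escape for non-ACGT
  bases;
* **plus-lines** — redundant in practice: classified as bare `+`, a mirror of
  the identifier, or (fallback) stored verbatim, so the stream is usually
  discarded and regenerated;
* **quality scores** — a ~40..94-symbol alphabet whose successive scores are
  strongly correlated: a context-mixing model in the PAQ/ZPAQ tradition
  predicts each of the 7 bits of a score from several score-history contexts
  through a learned logistic mixer.

All streams share one adaptive arithmetic (range) coder, and the payloads are
packed into a single checksummed archive.  Decompression inverts every step
exactly; `fq_verify()` proves it by byte comparison, never by assumption.

## The shared range coder

The coder is the seam everything else plugs into, so its contract is strict:
integer-only arithmetic (bit-identical payloads across platforms), a
32-bit range register with 16-bit probability resolution, byte-wise
renormalization at $2^{24}$, explicit carry propagation into the emitted
buffer, and a 4-byte flush.  Two interfaces are exposed: a binary one (used
natively by the quality codec) and a cumulative-frequency multi-symbol one
(used by the FCM codecs).  Probabilities are clamped to
$[1, 65535]/65536$, so no symbol ever reaches probability zero and the
decoder can never deadlock.

Two consequences matter in tests.  First, code length stays within a small
constant of the model entropy: the flush costs 32 bits and the
renormalization truncation about $2^{-9}$ bits/symbol, so a 10,000-symbol
i.i.d. source stays within 64 bits of $nH$.  Second, the decoder consumes
*exactly* the bytes the encoder emitted, which turns any truncation into a
detectable error instead of silently wrong output.

## Competing finite-context models for sequence

An order-$k$ FCM assigns
$P(s \mid \mathrm{ctx}) = \frac{c(\mathrm{ctx}, s) + \alpha}{\sum_{s'} c(\mathrm{ctx}, s') + 4\alpha}$
over the alphabet $\{A, C, G, T\}$.  Orders $\{2, 5, 8, 11\}$ run in
parallel (configurable); orders up to 8 use exact tables, higher orders a
24-bit hashed table, bounding memory deterministically.  Each model keeps an
exponentially decayed accumulator of the code length it *would* have paid
(decay 0.95, an effective window of ~20 bases); blending weights are
$w_m \propto 2^{-(\ell_m - \ell_{\min})}$.  Blending rather than hard
switching avoids coding the switch events; a single-order configuration is
available through `fq_codec_config(seq_orders = k)` and is used as the
ablation baseline in the tests.  Smoothing uses $\alpha = 1/16$: small
enough that a converged high-order context approaches certainty, large
enough to keep early mispredictions cheap.

Non-ACGT bases (N, rarely others) are coded as a per-position binary escape
flag (adaptive, conditioned on the previous flag) plus a literal byte in an
order-0 side model.  This keeps the FCM tables 4-symbol; for N-free data the
flag stream costs well under 0.001 bits/base.

## Identifier tokenization and delta coding

Identifiers are split into maximal digit runs (numeric fields, stored as
value + original width so leading zeros survive) and non-digit runs.
Consecutive records usually share a template (same field tags); numeric
fields are then reduced to differences (zig-zag varints), text fields to a
changed/same flag.  A template change re-baselines against an all-zeros
predecessor; a record with a numeric field wider than 255 characters falls
back to a raw literal.  Digit runs longer than 15 characters stay text —
beyond exact double-precision integer range — which costs nothing in
practice and keeps arithmetic exact.  The structural byte stream and the
text byte stream are each compressed with a single order-2 byte FCM; with
packed per-record flags the structural stream of a run of incrementing
identifiers is nearly deterministic and codes to under 2% of the raw bytes.

## Context mixing for quality scores

Quality scores correlate strongly with their recent predecessors, and that
correlation decays with distance.  Each score (offset-33, value 0–93) is
binarized to 7 bits, MSB first.  Six predictors map a context to a 12-bit
probability state:

1. the bit-tree node alone (order-0 floor model),
2. the previous score $q_1$,
3. the pair $(q_1, q_2)$,
4. the read position, quantized into 16 log-spaced buckets so
   variable-length long reads do not explode the table,
5. $(q_1, \max$ of the last 8 scores$)$,
6. the sign of $q_1 - q_2$.

A logistic mixer — weights selected by an 8-bucket quantization of $q_1$ —
combines the predictions in the stretched domain,
$p = \mathrm{squash}(\sum_i w_i\,\mathrm{stretch}(p_i))$ with
$\mathrm{stretch}(p) = \ln p/(1-p)$, and is trained online with
$w_i \mathrel{+}= \eta\,(b - p)\,\mathrm{stretch}(p_i)$, $\eta = 1/512$;
predictor states move toward the observed bit with rate $1/32$.  All of it
is fixed-point (12-bit probabilities, 16.16 weights), so encoder and decoder
trajectories are bit-identical.  Contexts reset at read boundaries; learned
tables persist across reads.  The order-0 predictor exists both as a floor
for the mixer and as the single-predictor ablation baseline — this is one
predictor more than a minimal five-context design, adopted because the
ablation configuration needs it anyway.

## The archive

One binary container holds everything needed for exact inversion: magic tag,
format version, flags (newline convention, plus-line mode), record count, a
64-bit FNV-1a checksum of the original file, and per stream the codec id,
its full parameter block (so decompression never depends on package
defaults), the payload length, a checksum of the *uncompressed* stream bytes
and a checksum of the *compressed* payload bytes.  The double checksum is
deliberate: corruption in a coder's final flush bytes can fall below symbol
resolution and decode to identical output, so payload checksums are verified
before any decoding, and every error is attributed to the stream it occurred
in.  Integers are little-endian fixed-width.  Random access and encryption
are out of scope.

## The synthetic generator

`fq_generate()` emulates the two benchmark read classes: Illumina-like
fixed-length short reads (default 100 bp, Phred range 0–40) and PacBio-like
variable-length long reads (log-normal lengths, median ~1 kb, minimum 50,
narrower 0–30 range and lower persistence, reflecting the platform's higher
error rate).  Sequences are i.i.d. ACGT with a per-file 200-base motif
re-inserted with 1% per-read probability — genomes are repetitive, and pure
noise would make the high-order models useless (a separate i.i.d. fixture
keeps the worst case covered) — plus optional N bases.

Quality strings follow a latent first-order Markov level with
stay-probability $s$ (default 0.9).  A move is a small $\pm1..3$ step half
the time and a fresh draw from the upper half of the quality band otherwise;
the redraws pin the stationary variance so the lag-1 autocorrelation of the
output increases with $s$ instead of tracking accumulated random-walk
variance.  On top of the level, each base gets independent discrete Gaussian
jitter (sd 2) and a deterministic down-drift of 2 Phred units per 100 bases.
The jitter matters: real Illumina quality streams compress at roughly 2:1 to
4:1, and a *noiseless* stay-0.9 chain would be an unrealistically easy
~10:1.  With jitter the generated streams land in that empirical band, which
is what makes the quality-codec band test meaningful.

Identifiers follow a template with an incrementing index; paired-end data is
emulated only through ` 1/1`-style suffixes since the compressor never uses
mate pairing.  Identical configuration + seed gives byte-identical output,
and the generator restores the caller's RNG state.

What the generator does **not** emulate: reference-derived sequence content
(no real genome, no coverage structure), realistic error models
(substitution/indel profiles), instrument tile/cycle artefacts, or quality
distributions with multimodal structure.  Passing the suite therefore shows
the pipeline is lossless and near-entropy on data with the *statistical
shape* of the benchmark classes, not that the absolute ratios on any real
dataset will match.

## Numerical choices and degenerate inputs

* Strict 4-line FASTQ; wrapped records, mixed newline conventions and files
  without a final newline are rejected with located errors — anything less
  would break the byte-exact contract.
* Empty files, empty streams and zero-length reads round-trip (a header-only
  archive); an empty symbol list costs exactly the 4-byte flush.
* Count tables halve on saturation (16-bit sequence counts, byte-FCM rows at
  ~60k total), keeping all frequencies inside the coder's 16-bit resolution.
* Blended sequence frequencies are quantized to a sum of exactly 65536 with
  every symbol at least 1; the remainder goes to the most probable symbol.
* Probabilities in the mixing path are 12-bit with tabulated
  stretch/squash; `cm_squash(cm_stretch(p))` is identity to within 1/256.

## Problem sizes in the test suite

The suite generates everything at run time: the fixture matrix uses 400
Illumina-like reads (100 of PacBio-like) per file across
platform × plus-mode × N-rate plus degenerate cases; coder optimality uses
10,000-symbol constructed sources; the quality band uses 1000 reads × 100
cycles over five seeds and monotonicity 500 × 100 per stay-probability; the
corruption scan flips every payload byte of a ~1.5 kB archive.  These sizes
were chosen as the smallest at which the measured quantities are stable.

## Known limitations

* The R entry points read a whole file per call.  The codecs themselves are
  single-pass adaptive, but a chunked streaming driver is future work, as is
  multi-threading.
* No random access into archives; decompression is all-or-nothing.
* `peak_memory()` uses `fork`/`wait4` and is POSIX-only.
* The archive format is this package's own (version-gated); it is not
  bit-compatible with any external tool's format.
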