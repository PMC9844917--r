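---
title: "Dynamic DNA QR coding: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic DNA QR coding: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddqr)
```

## The problem

DNA barcodes — short standardized marker sequences such as *rbcL*, *matK*,
*psbA-trnH*, ITS2 (plants) and COI (animals) — identify the biological origin
of a sample. Attaching a barcode sequence to a physical product label calls
for a compact, machine-readable representation: a QR symbol. A raw 600 bp
sequence is too large for a practical QR code, and general-purpose genomic
compressors (reference-based or context-modelling tools) are poorly matched
to single short sequences of wildly varying composition. `ddqr` implements a
reference-free scheme tuned to exactly this size range.

## The codec

A sequence over $\{A,C,G,T\}$ of length $L$ with base counts
$c_1 \ge c_2 \ge c_3 \ge c_4$ (the bases so ranked are called
$nt_1 \dots nt_4$) is encoded by the cheaper of two codes:

* **two-bit (binary) coding** — each base maps to its 2-bit rank code
  ($nt_1 = 00$, $nt_2 = 01$, $nt_3 = 10$, $nt_4 = 11$), payload exactly
  $2L$ bits;
* **static Huffman coding** — the fixed prefix code $nt_1 = 1$, $nt_2 = 01$,
  $nt_3 = 001$, $nt_4 = 000$, payload
  $c_1 + 2c_2 + 3(c_3 + c_4) = L + c_2 + 2(c_3 + c_4)$ bits, i.e.
  $f_1 + 2f_2 + 3(f_3 + f_4)$ bits per base on frequencies $f_i$.

Comparing the two payloads gives a clean algebraic selection rule: Huffman
wins exactly when $2c_1 + c_2 > L$. The encoder prepends a 3-bit scheme tag
(`000` Huffman, `111` binary), pads the stream with `'0'` bits to a multiple
of six, and maps each 6-bit group to the RFC 4648 standard Base64 alphabet.
The Base64 text is what a QR symbol carries.

### Header layout and the two profiles

A 3-bit tag alone does not make the stream decodable: the decoder must also
learn the base ranking. The header therefore carries a 6-bit **order field**
— the fixed 2-bit identifiers (A=00, C=01, G=10, T=11) of $nt_1, nt_2, nt_3$,
with $nt_4$ implied — giving a 9-bit header. This 9-bit layout is not an
arbitrary choice: under it the binary-regime output size is
$\lceil (2L + 9)/6 \rceil$ characters, which reproduces the reported mean
simulated compression rates exactly ($0.345$ at $L = 200$, $0.34$ at 300,
$0.3375$ at 400), so it is retained as the **paper profile** for all rate
analytics.

Zero-bit padding is, however, ambiguous at decode time: `00` is a valid
binary codeword and `000` a valid Huffman codeword, so up to two spurious
$nt_1$ (binary) or one spurious $nt_4$ (Huffman) can appear at the decoded
tail. Paper-profile decodes are greedy over the whole stream and carry a
`tail_ambiguous` attribute. The **robust profile** (the default for
encode/decode round trips) adds a 3-bit pad-count field (header 12 bits),
making decoding provably lossless; every ranking tie is broken
alphabetically (A < C < G < T) so encoding is a pure function of the
sequence.

The compression rate is defined as output Base64 characters divided by
input bases; smaller is better, with $1/3$ the asymptotic binary-regime
value and $1/6$ the absolute floor of a 1-bit-per-base code.

## QR representation

`render_qr()`/`read_qr()` implement byte-mode QR symbols (versions 1–40,
error-correction levels L/M/Q/H, default M, module size 10 px, quiet zone 4
modules) with Reed–Solomon block coding over $GF(256)$, penalty-scored mask
selection, and BCH-protected format/version information. The reader assumes
clean, axis-aligned images such as the package's own renders: it binarizes,
locates the grid from the bounding box and the top-left finder run, and then
applies format lookup, unmasking, de-interleaving and Reed–Solomon
correction (so moderately damaged symbols are still recovered). The
construction follows the standard symbology; the block-structure constants
are cross-checked in the test suite against the layout-derived codeword
totals and remainder bits of all 160 version/level combinations, and
round-trip and error-injection properties are tested throughout. No
independent scanner is bundled, so cross-reader interoperability is asserted
by construction rather than by test — the known limitation of this module.

## The simulation study

`generate_sequence(L, f, b)` draws a sequence in which base $b$ (default A)
has proportion $f \in [0.25, 1]$ and the remaining mass is split over the
other three bases by a flat Dirichlet draw on the scaled 3-simplex,
**conditioned on the dominant base staying modal** (draws in which a minor
proportion exceeds $f$ are rejected). The conditioning is deliberate: the
study design designates one base as "the most significant proportion", and
without it a minor base would dominate most draws at low $f$ — at $f = 0.25$
an unconditioned draw makes the Huffman branch fire in over 80% of
replicates and pulls the mean rate at $L = 200$ to about $0.31$ rather than
the binary-regime $0.345$ that defines the published study conditions. At
the $f = 0.25$ boundary the only composition whose maximum is $0.25$ is the
uniform one, which is used exactly. Positions are sampled i.i.d.;
`exact_counts = TRUE` instead realizes the drawn proportions as exact
integer counts (largest-remainder rounding) and permutes them.

`run_sweep()` tabulates mean and SD of the compression rate over a
(length × composition) grid — the defaults of 500 replicates per cell and
the 25–95% composition grid in 1% steps are the study conditions; sweeps in
the examples and tests use the same generator at smaller grids.
`ratio_series()` divides the mean DDQR rate by the mean rate of a plug-in
comparator (`function(seq) -> compressed size in characters`); an external
compressor such as GeCo3 can be wrapped as a subprocess adapter, but no
external tool is required and comparator failures skip the affected cell
with a warning. `detect_cutoff()` implements the sliding-window rule: over
an 11-point window covering lengths $i-10 \dots i$, the first $i$ at which
at least 6 of the 11 ratios exceed 1 declares the cutoff at $i - 5$. When
several replicate series are scanned, the reported threshold is the mean of
the per-series cutoffs, which is how non-integer thresholds arise.

## Real-data statistics

`read_fasta()` (backed by the Bioconductor FASTA reader) ingests marker
datasets; records with ambiguity codes are flagged and excluded from
statistics by default rather than silently altered, because a codec that
drops bases corrupts data. `apply_length_filter()` applies the barcode
pre-processing conventions — 150–600 bp inclusive for the four plant
markers, 100–700 bp for COI. `dataset_stats()` reports per-dataset record
count, mean length, mean compression rate and a rate histogram (bin width
0.005 over [0.15, 0.40] with overflow bins). Orientation checking and flank
trimming are out of scope: curated inputs are assumed. The GenBank-derived
marker datasets themselves (tens of thousands of records per marker) are
not redistributed with the package; `dataset_stats()` reproduces their
published averages only when the user supplies those files, and the test
suite says so explicitly rather than substituting synthetic data for the
claim.

## Numerical and design choices

* **Tie-breaks.** Equal base counts rank alphabetically; equal payload
  sizes select binary coding (fixed-width decode, smaller tail ambiguity).
* **Huffman codeword convention.** $nt_3 = 001$, $nt_4 = 000$; the swap of
  these two 3-bit codes changes no payload length, but one convention must
  be fixed for byte-exact output.
* **Bit order.** All fields are most-significant-bit first, matching
  left-to-right string concatenation; Base64 uses the RFC 4648 standard
  alphabet with no `=` characters (padding happens at the bit level).
* **Strict alphabet.** `N` and IUPAC ambiguity codes are rejected with
  position information, never dropped; batch interfaces expose an explicit
  skip-invalid choice at the record level.
* **Degenerate inputs.** Single-base sequences (Huffman payload 1 bit),
  length-1 sequences, and all-tie compositions are all well-defined and
  covered by exhaustive short-sequence round-trip tests.
* **Problem sizes.** The bundled checks use 500 replicates per simulation
  cell (matching the study conditions) at lengths 200–400, 10,000-sequence
  round-trip sweeps up to 1000 bp, and 200-payload QR round trips up to 500
  characters — sizes chosen so the full suite runs comfortably on a laptop
  while keeping the binomial noise far below the tolerances tested.

## What the synthetic generator does and does not show

The generator reproduces the compositional skew and length ranges of the
study design, so passing tests demonstrate bit-exact coding, losslessness,
and the closed-form rate behaviour on such sequences. Real barcode
sequences additionally have positional structure (codon bias, conserved
motifs, homopolymer runs) that a memoryless sampler does not emulate; none
of it affects this codec, whose payload depends only on base counts, but it
does affect context-modelling comparators, so simulated comparator ratios
should not be read as predictions for real data. Reproducing the published
per-marker real-data averages requires the original GenBank-derived files,
as noted above.
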