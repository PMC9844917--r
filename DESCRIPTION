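Package: ddqr
Title: Dynamic DNA QR Coding for Short Barcode Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free compression of short DNA barcode sequences
    (rbcL, matK, psbA-trnH, ITS2, COI and similar markers) by per-sequence
    dynamic selection between a fixed two-bit code and a static Huffman
    prefix code over frequency-ranked bases, followed by Base64 packing and
    rendering as a QR symbol. Includes a lossless decoding profile, a
    simulation engine for compression-rate sweeps over sequence length and
    base composition, a sliding-window detector for the length cutoff at
    which a comparator compressor overtakes the dynamic codec, FASTA batch
    statistics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
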