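# Constant tables of the QR symbology (ISO/IEC 18004): error-correction
# block structure per version/level and alignment-pattern center coordinates.
# Internal consistency of these tables against the computable module layout
# (codeword totals and remainder bits) is asserted in the test suite.

# Each entry: ec = EC codewords per block; blocks = vector of data-codeword
# counts, one element per block (group 1 then group 2).
qr_ec_entry <- function(ec, n1, d1, n2 = 0L, d2 = 0L) {
  list(ec = as.integer(ec), blocks = c(rep.int(as.integer(d1), n1), rep.int(as.integer(d2), n2)))
}

QR_EC_TABLE <- local({
  e <- qr_ec_entry
  # per version: list(L, M, Q, H)
  list(
    list(e(7, 1, 19), e(10, 1, 16), e(13, 1, 13), e(17, 1, 9)),
    list(e(10, 1, 34), e(16, 1, 28), e(22, 1, 22), e(28, 1, 16)),
    list(e(15, 1, 55), e(26, 1, 44), e(18, 2, 17), e(22, 2, 13)),
    list(e(20, 1, 80), e(18, 2, 32), e(26, 2, 24), e(16, 4, 9)),
    list(e(26, 1, 108), e(24, 2, 43), e(18, 2, 15, 2, 16), e(22, 2, 11, 2, 12)),
    list(e(18, 2, 68), e(16, 4, 27), e(24, 4, 19), e(28, 4, 15)),
    list(e(20, 2, 78), e(18, 4, 31), e(18, 2, 14, 4, 15), e(26, 4, 13, 1, 14)),
    list(e(24, 2, 97), e(22, 2, 38, 2, 39), e(22, 4, 18, 2, 19), e(26, 4, 14, 2, 15)),
    list(e(30, 2, 116), e(22, 3, 36, 2, 37), e(20, 4, 16, 4, 17), e(24, 4, 12, 4, 13)),
    list(e(18, 2, 68, 2, 69), e(26, 4, 43, 1, 44), e(24, 6, 19, 2, 20), e(28, 6, 15, 2, 16)),
    list(e(20, 4, 81), e(30, 1, 50, 4, 51), e(28, 4, 22, 4, 23), e(24, 3, 12, 8, 13)),
    list(e(24, 2, 92, 2, 93), e(22, 6, 36, 2, 37), e(26, 4, 20, 6, 21), e(28, 7, 14, 4, 15)),
    list(e(26, 4, 107), e(22, 8, 37, 1, 38), e(24, 8, 20, 4, 21), e(22, 12, 11, 4, 12)),
    list(e(30, 3, 115, 1, 116), e(24, 4, 40, 5, 41), e(20, 11, 16, 5, 17), e(24, 11, 12, 5, 13)),
    list(e(22, 5, 87, 1, 88), e(24, 5, 41, 5, 42), e(30, 5, 24, 7, 25), e(24, 11, 12, 7, 13)),
    list(e(24, 5, 98, 1, 99), e(28, 7, 45, 3, 46), e(24, 15, 19, 2, 20), e(30, 3, 15, 13, 16)),
    list(e(28, 1, 107, 5, 108), e(28, 10, 46, 1, 47), e(28, 1, 22, 15, 23), e(28, 2, 14, 17, 15)),
    list(e(30, 5, 120, 1, 121), e(26, 9, 43, 4, 44), e(28, 17, 22, 1, 23), e(28, 2, 14, 19, 15)),
    list(e(28, 3, 113, 4, 114), e(26, 3, 44, 11, 45), e(26, 17, 21, 4, 22), e(26, 9, 13, 16, 14)),
    list(e(28, 3, 107, 5, 108), e(26, 3, 41, 13, 42), e(30, 15, 24, 5, 25), e(28, 15, 15, 10, 16)),
    list(e(28, 4, 116, 4, 117), e(26, 17, 42), e(28, 17, 22, 6, 23), e(30, 19, 16, 6, 17)),
    list(e(28, 2, 111, 7, 112), e(28, 17, 46), e(30, 7, 24, 16, 25), e(24, 34, 13)),
    list(e(30, 4, 121, 5, 122), e(28, 4, 47, 14, 48), e(30, 11, 24, 14, 25), e(30, 16, 15, 14, 16)),
    list(e(30, 6, 117, 4, 118), e(28, 6, 45, 14, 46), e(30, 11, 24, 16, 25), e(30, 30, 16, 2, 17)),
    list(e(26, 8, 106, 4, 107), e(28, 8, 47, 13, 48), e(30, 7, 24, 22, 25), e(30, 22, 15, 13, 16)),
    list(e(28, 10, 114, 2, 115), e(28, 19, 46, 4, 47), e(28, 28, 22, 6, 23), e(30, 33, 16, 4, 17)),
    list(e(30, 8, 122, 4, 123), e(28, 22, 45, 3, 46), e(30, 8, 23, 26, 24), e(30, 12, 15, 28, 16)),
    list(e(30, 3, 117, 10, 118), e(28, 3, 45, 23, 46), e(30, 4, 24, 31, 25), e(30, 11, 15, 31, 16)),
    list(e(30, 7, 116, 7, 117), e(28, 21, 45, 7, 46), e(30, 1, 23, 37, 24), e(30, 19, 15, 26, 16)),
    list(e(30, 5, 115, 10, 116), e(28, 19, 47, 10, 48), e(30, 15, 24, 25, 25), e(30, 23, 15, 25, 16)),
    list(e(30, 13, 115, 3, 116), e(28, 2, 46, 29, 47), e(30, 42, 24, 1, 25), e(30, 23, 15, 28, 16)),
    list(e(30, 17, 115), e(28, 10, 46, 23, 47), e(30, 10, 24, 35, 25), e(30, 19, 15, 35, 16)),
    list(e(30, 17, 115, 1, 116), e(28, 14, 46, 21, 47), e(30, 29, 24, 19, 25), e(30, 11, 15, 46, 16)),
    list(e(30, 13, 115, 6, 116), e(28, 14, 46, 23, 47), e(30, 44, 24, 7, 25), e(30, 59, 16, 1, 17)),
    list(e(30, 12, 121, 7, 122), e(28, 12, 47, 26, 48), e(30, 39, 24, 14, 25), e(30, 22, 15, 41, 16)),
    list(e(30, 6, 121, 14, 122), e(28, 6, 47, 34, 48), e(30, 46, 24, 10, 25), e(30, 2, 15, 64, 16)),
    list(e(30, 17, 122, 4, 123), e(28, 29, 46, 14, 47), e(30, 49, 24, 10, 25), e(30, 24, 15, 46, 16)),
    list(e(30, 4, 122, 18, 123), e(28, 13, 46, 32, 47), e(30, 48, 24, 14, 25), e(30, 42, 15, 32, 16)),
    list(e(30, 20, 117, 4, 118), e(28, 40, 47, 7, 48), e(30, 43, 24, 22, 25), e(30, 10, 15, 67, 16)),
    list(e(30, 19, 118, 6, 119), e(28, 18, 47, 31, 48), e(30, 34, 24, 34, 25), e(30, 20, 15, 61, 16))
  )
})

QR_EC_LEVELS <- c("L", "M", "Q", "H")
# Format-information bit pairs for the EC level.
QR_EC_LEVEL_BITS <- list(L = c(0L, 1L), M = c(0L, 0L), Q = c(1L, 1L), H = c(1L, 0L))

QR_ALIGNMENT_POSITIONS <- list(
  integer(0),
  c(6, 18), c(6, 22), c(6, 26), c(6, 30), c(6, 34),
  c(6, 22, 38), c(6, 24, 42), c(6, 26, 46), c(6, 28, 50), c(6, 30, 54),
  c(6, 32, 58), c(6, 34, 62),
  c(6, 26, 46, 66), c(6, 26, 48, 70), c(6, 26, 50, 74), c(6, 30, 54, 78),
  c(6, 30, 56, 82), c(6, 30, 58, 86), c(6, 34, 62, 90),
  c(6, 28, 50, 72, 94), c(6, 26, 50, 74, 98), c(6, 30, 54, 78, 102),
  c(6, 28, 54, 80, 106), c(6, 32, 58, 84, 110), c(6, 30, 58, 86, 114),
  c(6, 34, 62, 90, 118),
  c(6, 26, 50, 74, 98, 122), c(6, 30, 54, 78, 102, 126),
  c(6, 26, 52, 78, 104, 130), c(6, 30, 56, 82, 108, 134),
  c(6, 34, 60, 86, 112, 138), c(6, 30, 58, 86, 114, 142),
  c(6, 34, 62, 90, 118, 146),
  c(6, 30, 54, 78, 102, 126, 150), c(6, 24, 50, 76, 102, 128, 154),
  c(6, 28, 54, 80, 106, 132, 158), c(6, 32, 58, 84, 110, 136, 162),
  c(6, 26, 54, 82, 110, 138, 166), c(6, 30, 58, 86, 114, 142, 170)
)

qr_size <- function(version) 17L + 4L * version

qr_total_codewords <- function(version, level) {
  entry <- QR_EC_TABLE[[version]][[match(level, QR_EC_LEVELS)]]
  sum(entry$blocks) + entry$ec * length(entry$blocks)
}

qr_data_codewords <- function(version, level) {
  sum(QR_EC_TABLE[[version]][[match(level, QR_EC_LEVELS)]]$blocks)
}

# Maximum byte-mode payload: 4 mode bits + 8/16 length bits + 8 per byte
# must fit in 8 * data codewords (terminator may be truncated).
qr_byte_capacity <- function(version, level) {
  bits <- 8L * qr_data_codewords(version, level)
  count_bits <- if (version <= 9L) 8L else 16L
  (bits - 4L - count_bits) %/% 8L
}
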