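test_that("normalization enforces the strict four-letter alphabet", {
  expect_identical(normalize_sequence("acgt"), "ACGT")
  expect_identical(normalize_sequence(" ac\ngt "), "ACGT")
  err <- expect_error(normalize_sequence("ACGN"), class = "ddqr_invalid_base_error")
  expect_equal(err$position, 4L)
  expect_equal(err$base, "N")
  expect_error(normalize_sequence(""), class = "ddqr_empty_sequence_error")
  expect_error(normalize_sequence("   "), class = "ddqr_empty_sequence_error")
  expect_error(normalize_sequence("ACG-T"), class = "ddqr_invalid_base_error")
})

test_that("frequency counting and ranking break ties alphabetically", {
  f <- count_frequencies("AAAT")
  expect_equal(unname(f$counts), c(3L, 0L, 0L, 1L))
  expect_equal(unname(f$freqs), c(0.75, 0, 0, 0.25))
  expect_equal(sum(count_frequencies("ACGT")$freqs), 1)

  expect_equal(rank_bases(count_frequencies("AAAT")), c("A", "T", "C", "G"))
  expect_equal(rank_bases(count_frequencies("ACGT")), c("A", "C", "G", "T"))
  counts <- c(A = 2L, C = 3L, G = 4L, T = 5L)
  expect_equal(rank_bases(counts), c("T", "G", "C", "A"))
})

test_that("expected Huffman cost is the mean code length of the (1,2,3,3) code", {
  f <- count_frequencies("AAAACCCGGT") # freqs 0.4, 0.3, 0.2, 0.1
  expect_equal(huffman_expected_cost(f), 0.4 + 2 * 0.3 + 3 * (0.2 + 0.1))
  expect_equal(huffman_expected_cost(count_frequencies("ACGT")), 2.25)
  expect_equal(huffman_expected_cost(count_frequencies("AAAA")), 1)
  # cost times length equals the exact Huffman payload bit count
  set.seed(41)
  for (i in 1:20) {
    s <- random_dna(sample(1:200, 1), prob = runif(4))
    f <- count_frequencies(s)
    ord <- rank_bases(f)
    expect_equal(
      huffman_expected_cost(f, ord) * f$length,
      length(encode_payload(s, ord, "huffman"))
    )
  }
})

test_that("payload bits match hand-derived codeword traces", {
  expect_equal(
    encode_payload("AAAT", c("A", "T", "C", "G"), "huffman"),
    c(1L, 1L, 1L, 0L, 1L)
  )
  expect_equal(
    encode_payload("ACGT", c("A", "C", "G", "T"), "binary"),
    c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L)
  )
  expect_equal(encode_payload("A", c("A", "C", "G", "T"), "huffman"), 1L)
  expect_error(
    encode_payload("ACGT", c("A", "C", "G", "G"), "binary"),
    class = "ddqr_invalid_base_error"
  )
})

test_that("scheme selection minimizes payload length and obeys the 2c1+c2 > L identity", {
  expect_equal(select_scheme("AAAT"), "huffman") # 5 vs 8 bits
  expect_equal(select_scheme("ACGT"), "binary") # 9 vs 8 bits
  # tie goes to binary: counts (2,2,1,1) give Huffman 2+4+3+3 = 12 = 2L
  expect_equal(select_scheme("AACCGT"), "binary")
  set.seed(42)
  for (i in 1:300) {
    s <- random_dna(sample(1:120, 1), prob = runif(4))
    scheme <- select_scheme(s)
    ord <- rank_bases(count_frequencies(s))
    hb <- length(encode_payload(s, ord, "huffman"))
    bb <- length(encode_payload(s, ord, "binary"))
    expect_equal(scheme, if (hb < bb) "huffman" else "binary")
    cs <- unname(sort(count_frequencies(s)$counts, decreasing = TRUE))
    expect_equal(scheme == "huffman", 2 * cs[1] + cs[2] > nchar(s))
  }
})

test_that("header packing lays out tag, order field and pad count", {
  expect_equal(
    pack_header("huffman", c("A", "T", "C", "G"), profile = "paper"),
    as.integer(strsplit("000001101", "")[[1]])
  )
  expect_equal(
    pack_header("binary", c("A", "C", "G", "T"), profile = "paper"),
    as.integer(strsplit("111000110", "")[[1]])
  )
  expect_equal(
    pack_header("binary", c("A", "C", "G", "T"), pad_count = 4, profile = "robust"),
    as.integer(strsplit("111000110100", "")[[1]])
  )
  expect_error(
    pack_header("binary", c("A", "C", "G", "T"), pad_count = 6, profile = "robust"),
    class = "ddqr_corrupt_header_error"
  )
})

test_that("Base64 packing pads with zero bits and inverts exactly", {
  bits <- as.integer(strsplit("000001101111010000", "")[[1]])
  expect_equal(bits_to_base64(bits), "BvQ")
  expect_equal(bits_to_base64(as.integer(strsplit("111000110000110110", "")[[1]])), "4w2")
  expect_equal(bits_to_base64(rep(0L, 6)), "A")
  expect_equal(base64_to_bits("BvQ"), bits)
  expect_equal(base64_to_bits("A"), rep(0L, 6))
  err <- expect_error(base64_to_bits("B*Q"), class = "ddqr_invalid_base64_error")
  expect_equal(err$position, 2L)
  set.seed(43)
  for (i in 1:50) {
    b <- sample(0:1, sample(1:200, 1), replace = TRUE)
    round <- base64_to_bits(bits_to_base64(b))
    expect_equal(round[seq_along(b)], b)
    expect_true(all(round[-seq_along(b)] == 0L))
    expect_equal(length(round) %% 6L, 0L)
  }
})

test_that("worked encodes are frozen and match the independent bit-trace oracle", {
  expect_equal(as.character(ddqr_encode("AAAT", profile = "paper")), "BvQ")
  expect_equal(as.character(ddqr_encode("ACGT", profile = "paper")), "4w2")
  expect_equal(as.character(ddqr_encode("AAAT", profile = "robust")), "Bp6")
  expect_equal(oracle_encode("AAAT", "paper"), "BvQ")
  expect_equal(oracle_encode("ACGT", "paper"), "4w2")
  expect_equal(oracle_encode("AAAT", "robust"), "Bp6")
  set.seed(44)
  for (i in 1:100) {
    s <- random_dna(sample(1:150, 1), prob = runif(4))
    expect_equal(as.character(ddqr_encode(s, "paper")), oracle_encode(s, "paper"))
    expect_equal(as.character(ddqr_encode(s, "robust")), oracle_encode(s, "robust"))
  }
})

test_that("robust profile round trips exhaustively for short sequences", {
  bases <- c("A", "C", "G", "T")
  for (L in 1:5) {
    combos <- do.call(expand.grid, c(rep(list(bases), L), stringsAsFactors = FALSE))
    seqs <- do.call(paste0, combos)
    for (s in seqs) {
      expect_identical(as.character(ddqr_decode(ddqr_encode(s))), s)
    }
  }
})

test_that("robust profile round trips random sequences of all compositions", {
  set.seed(45)
  for (i in 1:150) {
    s <- random_dna(sample(1:800, 1), prob = runif(4)^3 + 0.01)
    enc <- ddqr_encode(s)
    expect_identical(as.character(ddqr_decode(enc)), s)
    expect_false(attr(ddqr_decode(enc), "tail_ambiguous"))
  }
  # degenerate single-base runs (maximal Huffman benefit)
  for (L in c(1, 2, 3, 7, 100, 999)) {
    s <- strrep("G", L)
    expect_identical(as.character(ddqr_decode(ddqr_encode(s))), s)
  }
})

test_that("paper-profile decode is greedy over the padded tail and flags ambiguity", {
  dec <- ddqr_decode("BvQ", profile = "paper")
  # 4 pad zeros contain one complete '000' codeword, decoded as a spurious nt4
  expect_identical(as.character(dec), "AAATG")
  expect_true(attr(dec, "tail_ambiguous"))
  expect_identical(as.character(ddqr_decode("4w2", profile = "paper")), "ACGT")
  # binary decode may append at most two spurious nt1 bases
  set.seed(46)
  for (i in 1:60) {
    s <- random_dna(sample(4:300, 1))
    dec <- as.character(ddqr_decode(ddqr_encode(s, "paper"), profile = "paper"))
    expect_true(startsWith(dec, s))
    expect_lte(nchar(dec) - nchar(s), 2)
  }
})

test_that("corrupt headers are rejected with classed errors", {
  # first 6 bits 010000 -> scheme tag '010'
  expect_error(ddqr_decode("QAA", profile = "paper"), class = "ddqr_corrupt_header_error")
  # tag 000 with order field 00 00 .. -> duplicate base identifiers
  expect_error(ddqr_decode("AAA", profile = "paper"), class = "ddqr_corrupt_header_error")
  # robust header with pad_count = 6: bits 000 001101 110
  expect_error(ddqr_decode("Bu", profile = "robust"), class = "ddqr_corrupt_header_error")
  expect_error(ddqr_decode("B", profile = "robust"), class = "ddqr_corrupt_header_error")
})

test_that("encoding is deterministic and satisfies the output length formula", {
  set.seed(47)
  for (i in 1:80) {
    s <- random_dna(sample(1:500, 1), prob = runif(4))
    for (profile in c("paper", "robust")) {
      enc1 <- ddqr_encode(s, profile)
      enc2 <- ddqr_encode(s, profile)
      expect_identical(enc1, enc2)
      H <- if (profile == "robust") 12L else 9L
      P <- length(encode_payload(
        s, rank_bases(count_frequencies(s)),
        select_scheme(s)
      ))
      expect_equal(nchar(enc1), ceiling((H + P) / 6))
    }
  }
})

test_that("compression rate matches the closed forms for the binary regime", {
  expect_equal(compression_rate(strrep("ACGT", 50)), 69 / 200) # 0.345
  expect_equal(compression_rate(strrep("ACGT", 75)), 102 / 300) # 0.34
  expect_equal(compression_rate(strrep("ACGT", 100)), 135 / 400) # 0.3375
  expect_equal(compression_rate("AAAT"), 0.75)
})

test_that("rate never increases as composition mass moves to the dominant base", {
  # enumerate all descending compositions at L = 60 and shift one base of
  # mass from a minor class to nt1; the paper-profile rate must not increase
  L <- 60
  rate_of <- function(cnt) {
    s <- paste(rep(c("A", "C", "G", "T"), cnt), collapse = "")
    compression_rate(s, profile = "paper")
  }
  for (c1 in ceiling(L / 4):(L - 1)) {
    for (c2 in 0:min(c1, L - c1)) {
      for (c3 in 0:min(c2, L - c1 - c2)) {
        c4 <- L - c1 - c2 - c3
        if (c4 > c3) next
        from <- which(c(c1, c2, c3, c4) > 0)
        from <- from[from > 1]
        if (length(from) == 0) next
        j <- max(from)
        shifted <- c(c1, c2, c3, c4)
        shifted[1] <- shifted[1] + 1L
        shifted[j] <- shifted[j] - 1L
        expect_lte(rate_of(sort(shifted, decreasing = TRUE)), rate_of(c(c1, c2, c3, c4)))
      }
    }
  }
})
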