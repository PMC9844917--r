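test_that("EC block table is consistent with the module layout of every version", {
  # published remainder-bit counts per version; combined with the placement
  # order derived from the drawn function patterns this cross-checks both
  # the block table and the layout code
  remainder <- c(
    0, 7, 7, 7, 7, 7, 0, 0, 0, 0, 0, 0, 0, 3, 3, 3, 3, 3, 3, 3,
    4, 4, 4, 4, 4, 4, 4, 3, 3, 3, 3, 3, 3, 3, 0, 0, 0, 0, 0, 0
  )
  for (v in 1:40) {
    fp <- ddqr:::qr_function_patterns(v)
    available <- nrow(ddqr:::qr_placement_order(v, fp$reserved))
    totals <- vapply(
      c("L", "M", "Q", "H"),
      function(lev) ddqr:::qr_total_codewords(v, lev), integer(1)
    )
    expect_equal(length(unique(totals)), 1L) # same total at every level
    expect_equal(available - 8L * totals[["M"]], remainder[v])
  }
})

test_that("byte capacity grows with version and shrinks with EC level", {
  caps <- vapply(1:40, function(v) ddqr:::qr_byte_capacity(v, "M"), integer(1))
  expect_true(all(diff(caps) > 0))
  for (v in c(1, 10, 25, 40)) {
    by_level <- vapply(
      c("L", "M", "Q", "H"),
      function(lev) ddqr:::qr_byte_capacity(v, lev), integer(1)
    )
    expect_true(all(diff(by_level) < 0))
  }
})

test_that("format strings are a distance-separated BCH code", {
  formats <- ddqr:::qr_all_formats()
  expect_length(formats, 32L)
  for (i in seq_along(formats)) {
    for (j in seq_len(i - 1L)) {
      expect_gte(sum(formats[[i]] != formats[[j]]), 5L)
    }
  }
})

test_that("Reed-Solomon generator matches the canonical degree-10 polynomial", {
  g <- ddqr:::rs_generator(10L)
  expect_equal(
    ddqr:::gf_tables$log[g + 1L],
    c(0, 251, 67, 46, 61, 118, 70, 64, 94, 32, 45)
  )
})

test_that("Reed-Solomon corrects random symbol errors up to the design bound", {
  set.seed(51)
  for (i in 1:30) {
    n_ec <- sample(c(10L, 16L, 22L, 30L), 1)
    data <- sample(0:255, sample(10:60, 1), replace = TRUE)
    cw <- c(data, ddqr:::rs_encode_block(data, n_ec))
    n_err <- sample(0:(n_ec %/% 2L), 1)
    pos <- sample(seq_along(cw), n_err)
    cw_bad <- cw
    cw_bad[pos] <- bitwXor(cw_bad[pos], sample(1:255, n_err, replace = TRUE))
    expect_equal(ddqr:::rs_correct_block(cw_bad, n_ec), cw)
  }
})

test_that("QR symbols round trip across payload sizes, levels and pixel scales", {
  set.seed(52)
  alpha <- c(LETTERS, letters, as.character(0:9), "+", "/")
  cases <- expand.grid(
    len = c(1, 7, 25, 120, 520, 1100),
    level = c("L", "M", "Q", "H"),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(cases))) {
    payload <- paste(sample(alpha, cases$len[k], replace = TRUE), collapse = "")
    img <- render_qr(payload,
      error_correction = cases$level[k],
      module_pixel_size = sample(c(1, 3, 10), 1),
      border_modules = sample(0:4, 1)
    )
    expect_identical(read_qr(img), payload)
  }
})

test_that("rendered PNG files decode back to their payload", {
  path <- tempfile(fileext = ".png")
  on.exit(unlink(path))
  render_qr("BvQ", path = path)
  expect_identical(read_qr(path), "BvQ")
  render_qr("4w2", path = path, error_correction = "H")
  expect_identical(read_qr(path), "4w2")
})

test_that("payloads beyond symbol capacity and empty payloads are rejected", {
  expect_error(render_qr(""), class = "ddqr_empty_sequence_error")
  big <- strrep("A", 5000)
  err <- expect_error(render_qr(big, error_correction = "H"), class = "ddqr_capacity_error")
  expect_equal(err$max_bytes, 1273L) # version 40-H byte-mode capacity
})

test_that("the reader rejects blank, non-square and multi-symbol images", {
  expect_error(read_qr(matrix(1, 40, 40)), class = "ddqr_no_symbol_error")
  smudge <- matrix(1, 60, 80)
  smudge[10:20, 10:50] <- 0
  expect_error(read_qr(smudge), class = "ddqr_no_symbol_error")
  # four copies of a version-1 symbol tiled with a 3-module gap form a
  # 45-module square that passes the grid checks but has 12 finder patterns
  one <- render_qr("BvQ", module_pixel_size = 1, border_modules = 0)
  stopifnot(nrow(one) == 21)
  tiled <- matrix(1, 45, 45)
  for (r0 in c(0, 24)) {
    for (c0 in c(0, 24)) {
      tiled[r0 + 1:21, c0 + 1:21] <- one
    }
  }
  expect_error(read_qr(tiled), class = "ddqr_ambiguous_symbol_error")
})

test_that("damaged symbols are repaired by error correction", {
  set.seed(53)
  payload <- "DdqrEC/test+123"
  img <- render_qr(payload,
    error_correction = "H",
    module_pixel_size = 1, border_modules = 0
  )
  mat <- img < 0.5
  n <- nrow(mat)
  flips <- cbind(sample(9:(n - 1), 6, TRUE), sample(9:(n - 1), 6, TRUE))
  mat[flips] <- !mat[flips]
  expect_identical(ddqr:::qr_read_matrix(mat), payload)
})

test_that("DNA sequences survive the full encode-render-scan-decode chain", {
  set.seed(54)
  for (L in c(1, 30, 250, 600)) {
    s <- random_dna(L, prob = runif(4) + 0.05)
    img <- render_qr(ddqr_encode(s, profile = "robust"))
    expect_identical(as.character(ddqr_decode(read_qr(img), profile = "robust")), s)
  }
})
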