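# QR symbol construction and module-matrix decoding (byte mode, versions
# 1-40, all four EC levels, penalty-based mask selection). Matrices are
# logical with TRUE = dark; indices below are 0-based (row, col) with origin
# at the top-left, converted to R's 1-based indexing at the point of access.

qr_set <- function(mat, r, c, value) {
  mat[cbind(r + 1L, c + 1L)] <- value
  mat
}

# 15-bit format string (MSB first) for an EC level and mask id.
qr_format_bits <- function(level, mask) {
  data <- c(QR_EC_LEVEL_BITS[[level]], int_to_bits(mask, 3L))
  rem <- c(data, integer(10L))
  gen <- int_to_bits(0x537, 11L)
  for (i in 1:5) {
    if (rem[i] == 1L) rem[i:(i + 10L)] <- bitwXor(rem[i:(i + 10L)], gen)
  }
  bitwXor(c(data, rem[6:15]), int_to_bits(0x5412, 15L))
}

# All 32 valid format strings, built on first use (keyed "L0".."H7").
qr_all_formats <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      out <- list()
      for (level in QR_EC_LEVELS) {
        for (mask in 0:7) {
          out[[paste0(level, mask)]] <- qr_format_bits(level, mask)
        }
      }
      cache <<- out
    }
    cache
  }
})

# 18-bit version information string, MSB first (versions >= 7).
qr_version_bits <- function(version) {
  data <- int_to_bits(version, 6L)
  rem <- c(data, integer(12L))
  gen <- int_to_bits(0x1F25, 13L)
  for (i in 1:6) {
    if (rem[i] == 1L) rem[i:(i + 12L)] <- bitwXor(rem[i:(i + 12L)], gen)
  }
  c(data, rem[7:18])
}

# Function-pattern skeleton: list(modules = logical matrix with the fixed
# patterns drawn, reserved = logical matrix TRUE where data must not go).
qr_function_patterns <- function(version) {
  n <- qr_size(version)
  mod <- matrix(FALSE, n, n)
  res <- matrix(FALSE, n, n)

  draw_finder <- function(mod, res, r0, c0) {
    for (dr in -1:7) {
      for (dc in -1:7) {
        r <- r0 + dr
        c <- c0 + dc
        if (r < 0L || c < 0L || r >= n || c >= n) next
        inside <- dr >= 0L && dr <= 6L && dc >= 0L && dc <= 6L
        dark <- inside && (max(abs(dr - 3L), abs(dc - 3L)) != 2L)
        mod[r + 1L, c + 1L] <- dark
        res[r + 1L, c + 1L] <- TRUE
      }
    }
    list(mod, res)
  }
  for (pos in list(c(0L, 0L), c(0L, n - 7L), c(n - 7L, 0L))) {
    tmp <- draw_finder(mod, res, pos[1L], pos[2L])
    mod <- tmp[[1L]]
    res <- tmp[[2L]]
  }

  # timing patterns
  idx <- 8:(n - 9L)
  mod[7L, idx + 1L] <- idx %% 2L == 0L
  mod[idx + 1L, 7L] <- idx %% 2L == 0L
  res[7L, idx + 1L] <- TRUE
  res[idx + 1L, 7L] <- TRUE

  # alignment patterns
  centers <- QR_ALIGNMENT_POSITIONS[[version]]
  for (r0 in centers) {
    for (c0 in centers) {
      # the three patterns that would collide with finder corners are omitted
      # (patterns straddling the timing lines are kept and coincide with them)
      if ((r0 <= 8L && c0 <= 8L) || (r0 <= 8L && c0 >= n - 9L) ||
        (r0 >= n - 9L && c0 <= 8L)) {
        next
      }
      for (dr in -2:2) {
        for (dc in -2:2) {
          dark <- max(abs(dr), abs(dc)) != 1L
          mod[r0 + dr + 1L, c0 + dc + 1L] <- dark
          res[r0 + dr + 1L, c0 + dc + 1L] <- TRUE
        }
      }
    }
  }

  # dark module
  mod[4L * version + 9L + 1L, 9L] <- TRUE
  res[4L * version + 9L + 1L, 9L] <- TRUE

  # reserve format information areas
  fmt <- qr_format_positions(n)
  res[cbind(fmt$copy1[, 1L] + 1L, fmt$copy1[, 2L] + 1L)] <- TRUE
  res[cbind(fmt$copy2[, 1L] + 1L, fmt$copy2[, 2L] + 1L)] <- TRUE

  # reserve version information areas
  if (version >= 7L) {
    vp <- qr_version_positions(n)
    res[cbind(vp$bl[, 1L] + 1L, vp$bl[, 2L] + 1L)] <- TRUE
    res[cbind(vp$tr[, 1L] + 1L, vp$tr[, 2L] + 1L)] <- TRUE
  }

  list(modules = mod, reserved = res)
}

# Module coordinates (0-based) holding the two format-information copies,
# one row per bit, MSB first.
qr_format_positions <- function(n) {
  copy1 <- rbind(
    cbind(8L, c(0:5, 7L)),
    c(8L, 8L),
    c(7L, 8L),
    cbind(5:0, 8L)
  )
  copy2 <- rbind(
    cbind((n - 1L):(n - 7L), 8L),
    cbind(8L, (n - 8L):(n - 1L))
  )
  list(copy1 = copy1, copy2 = copy2)
}

# Version-information module coordinates (0-based), one row per bit in the
# order b17..b0 is NOT used; order here is LSB-first column-major (bottom
# left) and its transpose (top right), the conventional layout.
qr_version_positions <- function(n) {
  # LSB-first traversal: for bit index i (0 = LSB), bl position is
  # row n-11 + (i mod 3), col i %/% 3; tr is the transpose.
  i <- 0:17
  bl <- cbind(n - 11L + i %% 3L, i %/% 3L)
  tr <- cbind(i %/% 3L, n - 11L + i %% 3L)
  list(bl = bl, tr = tr)
}

# Zigzag placement order of data modules: matrix of 0-based (row, col).
qr_placement_order <- function(version, reserved) {
  n <- qr_size(version)
  coords <- matrix(0L, nrow = n * n, ncol = 2L)
  k <- 0L
  col <- n - 1L
  upward <- TRUE
  while (col > 0L) {
    if (col == 6L) col <- col - 1L # skip the timing column entirely
    rows <- if (upward) (n - 1L):0L else 0:(n - 1L)
    for (r in rows) {
      for (c in c(col, col - 1L)) {
        if (!reserved[r + 1L, c + 1L]) {
          k <- k + 1L
          coords[k, ] <- c(r, c)
        }
      }
    }
    upward <- !upward
    col <- col - 2L
  }
  coords[seq_len(k), , drop = FALSE]
}

qr_mask_matrix <- function(mask, n) {
  r <- matrix(0:(n - 1L), n, n)
  c <- matrix(0:(n - 1L), n, n, byrow = TRUE)
  switch(as.character(mask),
    "0" = (r + c) %% 2L == 0L,
    "1" = r %% 2L == 0L,
    "2" = c %% 3L == 0L,
    "3" = (r + c) %% 3L == 0L,
    "4" = (r %/% 2L + c %/% 3L) %% 2L == 0L,
    "5" = (r * c) %% 2L + (r * c) %% 3L == 0L,
    "6" = ((r * c) %% 2L + (r * c) %% 3L) %% 2L == 0L,
    "7" = ((r + c) %% 2L + (r * c) %% 3L) %% 2L == 0L
  )
}

# Standard mask-evaluation penalty (rules N1-N4).
qr_penalty <- function(mat) {
  n <- nrow(mat)
  score <- 0L
  run_penalty <- function(v) {
    r <- rle(v)
    sum(ifelse(r$lengths >= 5L, 3L + (r$lengths - 5L), 0L))
  }
  finder_penalty <- function(v) {
    s <- paste(as.integer(v), collapse = "")
    hits <- 0L
    for (pat in c("10111010000", "00001011101")) {
      start <- 1L
      repeat {
        i <- regexpr(pat, substr(s, start, nchar(s)), fixed = TRUE)
        if (i == -1L) break
        hits <- hits + 1L
        start <- start + i # overlapping search
      }
    }
    hits
  }
  n3 <- 0L
  for (i in seq_len(n)) {
    score <- score + run_penalty(mat[i, ]) + run_penalty(mat[, i])
    n3 <- n3 + finder_penalty(mat[i, ]) + finder_penalty(mat[, i])
  }
  blocks <- mat[-n, -n] & mat[-1L, -n] & mat[-n, -1L] & mat[-1L, -1L]
  same_light <- (!mat[-n, -n]) & (!mat[-1L, -n]) & (!mat[-n, -1L]) & (!mat[-1L, -1L])
  score <- score + 3L * (sum(blocks) + sum(same_light))
  score <- score + 40L * n3
  dark_pct <- 100 * sum(mat) / (n * n)
  score + 10L * (abs(trunc(dark_pct) - 50L) %/% 5L)
}

# Byte-mode bitstream: mode, count, data, terminator, byte padding.
qr_data_bitstream <- function(bytes, version, level) {
  n_data <- qr_data_codewords(version, level)
  count_bits <- if (version <= 9L) 8L else 16L
  bits <- c(
    c(0L, 1L, 0L, 0L),
    int_to_bits(length(bytes), count_bits),
    unlist(lapply(bytes, int_to_bits, width = 8L), use.names = FALSE)
  )
  capacity <- 8L * n_data
  stopifnot(length(bits) <= capacity)
  bits <- c(bits, integer(min(4L, capacity - length(bits)))) # terminator
  if (length(bits) %% 8L != 0L) {
    bits <- c(bits, integer(8L - length(bits) %% 8L))
  }
  pad_bytes <- c(236L, 17L)
  i <- 1L
  while (length(bits) < capacity) {
    bits <- c(bits, int_to_bits(pad_bytes[i], 8L))
    i <- 3L - i
  }
  bits
}

bits_to_bytes <- function(bits) {
  m <- matrix(bits, nrow = 8L)
  as.integer(2L^(7:0) %*% m)
}

# Split data codewords into RS blocks, append EC, interleave.
qr_interleave <- function(data_cw, version, level) {
  entry <- QR_EC_TABLE[[version]][[match(level, QR_EC_LEVELS)]]
  stopifnot(length(data_cw) == sum(entry$blocks))
  blocks <- list()
  pos <- 0L
  for (len in entry$blocks) {
    blocks[[length(blocks) + 1L]] <- data_cw[(pos + 1L):(pos + len)]
    pos <- pos + len
  }
  ec_blocks <- lapply(blocks, rs_encode_block, n_ec = entry$ec)
  inter <- integer(0)
  for (i in seq_len(max(entry$blocks))) {
    for (b in blocks) if (i <= length(b)) inter <- c(inter, b[i])
  }
  for (i in seq_len(entry$ec)) {
    for (b in ec_blocks) inter <- c(inter, b[i])
  }
  inter
}

qr_deinterleave <- function(codewords, version, level) {
  entry <- QR_EC_TABLE[[version]][[match(level, QR_EC_LEVELS)]]
  n_blocks <- length(entry$blocks)
  data_cw <- vector("list", n_blocks)
  idx <- 1L
  for (i in seq_len(max(entry$blocks))) {
    for (b in seq_len(n_blocks)) {
      if (i <= entry$blocks[b]) {
        data_cw[[b]] <- c(data_cw[[b]], codewords[idx])
        idx <- idx + 1L
      }
    }
  }
  ec_cw <- vector("list", n_blocks)
  for (i in seq_len(entry$ec)) {
    for (b in seq_len(n_blocks)) {
      ec_cw[[b]] <- c(ec_cw[[b]], codewords[idx])
      idx <- idx + 1L
    }
  }
  list(data = data_cw, ec = ec_cw, n_ec = entry$ec)
}

# Build the module matrix for a text payload. Returns a logical matrix with
# attributes version, level, mask.
qr_build_matrix <- function(text, level = "M") {
  stopifnot(level %in% QR_EC_LEVELS)
  bytes <- as.integer(charToRaw(text))
  version <- NA_integer_
  for (v in 1:40) {
    if (length(bytes) <= qr_byte_capacity(v, level)) {
      version <- v
      break
    }
  }
  if (is.na(version)) {
    stop_ddqr(
      "ddqr_capacity_error",
      sprintf(
        "payload of %d bytes exceeds QR capacity at level %s (max %d)",
        length(bytes), level, qr_byte_capacity(40L, level)
      ),
      max_bytes = qr_byte_capacity(40L, level)
    )
  }
  n <- qr_size(version)
  fp <- qr_function_patterns(version)
  order <- qr_placement_order(version, fp$reserved)

  data_bits <- qr_data_bitstream(bytes, version, level)
  codewords <- qr_interleave(bits_to_bytes(data_bits), version, level)
  stream <- unlist(lapply(codewords, int_to_bits, width = 8L), use.names = FALSE)
  stopifnot(nrow(order) >= length(stream), nrow(order) - length(stream) <= 7L)
  stream <- c(stream, integer(nrow(order) - length(stream))) # remainder bits

  fmt_pos <- qr_format_positions(n)
  best <- NULL
  for (mask in 0:7) {
    mat <- fp$modules
    mm <- qr_mask_matrix(mask, n)
    vals <- xor(stream == 1L, mm[cbind(order[, 1L] + 1L, order[, 2L] + 1L)])
    mat[cbind(order[, 1L] + 1L, order[, 2L] + 1L)] <- vals
    fb <- qr_format_bits(level, mask) == 1L
    mat[cbind(fmt_pos$copy1[, 1L] + 1L, fmt_pos$copy1[, 2L] + 1L)] <- fb
    mat[cbind(fmt_pos$copy2[, 1L] + 1L, fmt_pos$copy2[, 2L] + 1L)] <- fb
    if (version >= 7L) {
      vb <- qr_version_bits(version)
      vlsb <- rev(vb) == 1L # positions are LSB-first
      vp <- qr_version_positions(n)
      mat[cbind(vp$bl[, 1L] + 1L, vp$bl[, 2L] + 1L)] <- vlsb
      mat[cbind(vp$tr[, 1L] + 1L, vp$tr[, 2L] + 1L)] <- vlsb
    }
    p <- qr_penalty(mat)
    if (is.null(best) || p < best$penalty) {
      best <- list(mat = mat, penalty = p, mask = mask)
    }
  }
  structure(best$mat, version = version, level = level, mask = best$mask)
}

# Decode a module matrix back to its text payload.
qr_read_matrix <- function(mat) {
  n <- nrow(mat)
  if (n != ncol(mat) || n < 21L || (n - 17L) %% 4L != 0L) {
    stop_ddqr("ddqr_no_symbol_error", "matrix is not a QR module grid")
  }
  version <- (n - 17L) %/% 4L
  fmt_pos <- qr_format_positions(n)
  read_fmt <- function(pos) as.integer(mat[cbind(pos[, 1L] + 1L, pos[, 2L] + 1L)])
  candidates <- vapply(
    qr_all_formats(),
    function(f) {
      min(
        sum(f != read_fmt(fmt_pos$copy1)),
        sum(f != read_fmt(fmt_pos$copy2))
      )
    },
    numeric(1L)
  )
  pick <- names(candidates)[which.min(candidates)]
  if (min(candidates) > 3L) {
    stop_ddqr("ddqr_no_symbol_error", "format information unreadable")
  }
  level <- substr(pick, 1L, 1L)
  mask <- as.integer(substr(pick, 2L, 2L))

  fp <- qr_function_patterns(version)
  order <- qr_placement_order(version, fp$reserved)
  mm <- qr_mask_matrix(mask, n)
  bits <- as.integer(xor(
    mat[cbind(order[, 1L] + 1L, order[, 2L] + 1L)],
    mm[cbind(order[, 1L] + 1L, order[, 2L] + 1L)]
  ))
  total_cw <- qr_total_codewords(version, level)
  codewords <- bits_to_bytes(bits[seq_len(8L * total_cw)])
  parts <- qr_deinterleave(codewords, version, level)
  data_cw <- integer(0)
  for (b in seq_along(parts$data)) {
    corrected <- rs_correct_block(c(parts$data[[b]], parts$ec[[b]]), parts$n_ec)
    if (is.null(corrected)) {
      stop_ddqr("ddqr_no_symbol_error", "uncorrectable error-correction block")
    }
    data_cw <- c(data_cw, corrected[seq_along(parts$data[[b]])])
  }
  dbits <- unlist(lapply(data_cw, int_to_bits, width = 8L), use.names = FALSE)
  if (!identical(dbits[1:4], c(0L, 1L, 0L, 0L))) {
    stop_ddqr("ddqr_no_symbol_error", "unsupported QR mode (only byte mode is produced)")
  }
  count_bits <- if (version <= 9L) 8L else 16L
  count <- bits_to_int(dbits[5:(4L + count_bits)])
  start <- 4L + count_bits
  if (start + 8L * count > length(dbits)) {
    stop_ddqr("ddqr_no_symbol_error", "truncated byte-mode segment")
  }
  bytes <- bits_to_bytes(dbits[(start + 1L):(start + 8L * count)])
  rawToChar(as.raw(bytes))
}
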