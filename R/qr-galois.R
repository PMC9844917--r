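# GF(256) arithmetic (primitive polynomial x^8+x^4+x^3+x^2+1, 0x11D) and
# Reed-Solomon encoding/decoding as used by QR symbols.

gf_tables <- local({
  exp_t <- integer(512L)
  log_t <- integer(256L)
  x <- 1L
  for (i in 0:254) {
    exp_t[i + 1L] <- x
    log_t[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwXor(x, 285L) # 0x11D
  }
  exp_t[256:510] <- exp_t[1:255] # wraparound so exp[(a+b) mod 255] is implicit
  list(exp = exp_t, log = log_t)
})

gf_mul <- function(a, b) {
  out <- integer(length(a) * 0L + max(length(a), length(b)))
  a <- rep_len(as.integer(a), length(out))
  b <- rep_len(as.integer(b), length(out))
  nz <- a != 0L & b != 0L
  out[nz] <- gf_tables$exp[gf_tables$log[a[nz] + 1L] + gf_tables$log[b[nz] + 1L] + 1L]
  out
}

gf_inv <- function(a) {
  stopifnot(all(a != 0L))
  gf_tables$exp[(255L - gf_tables$log[a + 1L]) %% 255L + 1L]
}

gf_pow <- function(p) gf_tables$exp[p %% 255L + 1L] # alpha^p

# Polynomials are integer vectors, highest-degree coefficient first.
gf_poly_mul <- function(p, q) {
  out <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    out[i:(i + length(q) - 1L)] <- bitwXor(
      out[i:(i + length(q) - 1L)], gf_mul(p[i], q)
    )
  }
  out
}

# Generator polynomial (x - a^0)(x - a^1)...(x - a^(n-1)).
rs_generator <- function(n_ec) {
  g <- 1L
  for (i in 0:(n_ec - 1L)) g <- gf_poly_mul(g, c(1L, gf_pow(i)))
  g
}

# EC codewords for a data block: remainder of data * x^n_ec divided by g(x).
rs_encode_block <- function(data, n_ec) {
  gen <- rs_generator(n_ec)
  rem <- c(as.integer(data), integer(n_ec))
  for (i in seq_along(data)) {
    coef <- rem[i]
    if (coef != 0L) {
      idx <- i:(i + n_ec)
      rem[idx] <- bitwXor(rem[idx], gf_mul(coef, gen))
    }
  }
  rem[(length(data) + 1L):(length(data) + n_ec)]
}

gf_poly_eval <- function(p, x) {
  y <- 0L
  for (coef in p) y <- bitwXor(gf_mul(y, x), coef)
  y
}

# Syndrome-based RS error correction (Berlekamp-Massey + Chien + Forney).
# Returns the corrected full codeword (data + ec) or NULL when uncorrectable.
rs_correct_block <- function(codeword, n_ec) {
  cw <- as.integer(codeword)
  synd <- vapply(0:(n_ec - 1L), function(i) gf_poly_eval(cw, gf_pow(i)), integer(1L))
  if (all(synd == 0L)) {
    return(cw)
  }
  # Berlekamp-Massey: error locator sigma (lowest degree first here)
  sigma <- 1L
  b <- 1L
  L <- 0L
  m <- 1L
  bb <- 1L
  for (n in 0:(n_ec - 1L)) {
    d <- synd[n + 1L]
    if (L > 0L) {
      for (i in 1:L) {
        d <- bitwXor(d, gf_mul(sigma[i + 1L], synd[n - i + 1L]))
      }
    }
    if (d == 0L) {
      m <- m + 1L
    } else if (2L * L <= n) {
      t <- sigma
      coef <- gf_mul(d, gf_inv(bb))
      shifted <- c(integer(m), gf_mul(coef, b))
      len <- max(length(sigma), length(shifted))
      sigma <- bitwXor(
        c(sigma, integer(len - length(sigma))),
        c(shifted, integer(len - length(shifted)))
      )
      L <- n + 1L - L
      b <- t
      bb <- d
      m <- 1L
    } else {
      coef <- gf_mul(d, gf_inv(bb))
      shifted <- c(integer(m), gf_mul(coef, b))
      len <- max(length(sigma), length(shifted))
      sigma <- bitwXor(
        c(sigma, integer(len - length(sigma))),
        c(shifted, integer(len - length(shifted)))
      )
      m <- m + 1L
    }
  }
  sigma <- sigma[1:(L + 1L)]
  if (L > n_ec %/% 2L) {
    return(NULL)
  }
  # Chien search over codeword positions. Position j (0 = first transmitted
  # codeword) corresponds to power n-1-j of alpha.
  n_total <- length(cw)
  err_pos <- integer(0)
  for (j in 0:(n_total - 1L)) {
    xinv <- gf_pow(-(n_total - 1L - j))
    # evaluate sigma (lowest degree first) at x = xinv
    acc <- 0L
    xp <- 1L
    for (c_i in sigma) {
      acc <- bitwXor(acc, gf_mul(c_i, xp))
      xp <- gf_mul(xp, xinv)
    }
    if (acc == 0L) err_pos <- c(err_pos, j)
  }
  if (length(err_pos) != L) {
    return(NULL)
  }
  # Forney: omega(x) = [S(x) * sigma(x)] mod x^n_ec, S lowest degree first.
  prod_poly <- integer(n_ec)
  for (i in seq_along(sigma)) {
    if (sigma[i] == 0L) next
    for (k in seq_len(n_ec - i + 1L)) {
      prod_poly[i + k - 1L] <- bitwXor(prod_poly[i + k - 1L], gf_mul(sigma[i], synd[k]))
    }
  }
  sigma_deriv <- sigma[seq(2L, length(sigma), by = 2L)] # odd-power coeffs
  for (j in err_pos) {
    xinv <- gf_pow(-(n_total - 1L - j)) # X_i^{-1}
    num <- 0L
    xp <- 1L
    for (c_i in prod_poly) {
      num <- bitwXor(num, gf_mul(c_i, xp))
      xp <- gf_mul(xp, xinv)
    }
    den <- 0L
    xp <- 1L
    x2 <- gf_mul(xinv, xinv)
    for (c_i in sigma_deriv) {
      den <- bitwXor(den, gf_mul(c_i, xp))
      xp <- gf_mul(xp, x2)
    }
    if (den == 0L) {
      return(NULL)
    }
    # e_j = X_j * Omega(X_j^{-1}) / Lambda'(X_j^{-1})  (syndromes start at a^0)
    magnitude <- gf_mul(gf_pow(n_total - 1L - j), gf_mul(num, gf_inv(den)))
    cw[j + 1L] <- bitwXor(cw[j + 1L], magnitude)
  }
  # verify
  synd2 <- vapply(0:(n_ec - 1L), function(i) gf_poly_eval(cw, gf_pow(i)), integer(1L))
  if (any(synd2 != 0L)) {
    return(NULL)
  }
  cw
}
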