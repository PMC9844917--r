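# Independent oracles used to freeze expected values. These deliberately
# share no code with the package: they work on character bit-strings and
# name-indexed lookup tables instead of integer bit vectors.

random_dna <- function(length, prob = NULL) {
  if (is.null(prob)) prob <- rep(0.25, 4)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = prob),
    collapse = ""
  )
}

# Brute-force bit-trace encoder: builds the bitstream as a character string
# via per-base table lookup and converts 6-bit chunks with strtoi().
oracle_encode <- function(seq, profile = c("paper", "robust")) {
  profile <- match.arg(profile)
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  cnt <- sapply(bases, function(b) sum(chars == b))
  ord <- bases[order(-cnt)] # stable sort: ties stay alphabetical
  two <- c("00", "01", "10", "11")
  huf <- c("1", "01", "001", "000")
  names(two) <- names(huf) <- ord
  pb <- paste(two[chars], collapse = "")
  ph <- paste(huf[chars], collapse = "")
  if (nchar(ph) < nchar(pb)) {
    tag <- "000"
    payload <- ph
  } else {
    tag <- "111"
    payload <- pb
  }
  id <- c(A = "00", C = "01", G = "10", T = "11")
  header <- paste0(tag, id[ord[1]], id[ord[2]], id[ord[3]])
  if (profile == "robust") {
    pad <- (6 - (nchar(header) + 3 + nchar(payload)) %% 6) %% 6
    header <- paste0(header, c("000", "001", "010", "011", "100", "101")[pad + 1])
  }
  bits <- paste0(header, payload)
  bits <- paste0(bits, strrep("0", (6 - nchar(bits) %% 6) %% 6))
  alpha <- c(LETTERS, letters, as.character(0:9), "+", "/")
  starts <- seq(1, nchar(bits), by = 6)
  idx <- vapply(starts, function(i) strtoi(substr(bits, i, i + 5), base = 2L), integer(1))
  paste(alpha[idx + 1], collapse = "")
}

# Exhaustive window scan over an embedded ratio matrix; structurally unlike
# the sequential scan in detect_cutoff().
oracle_cutoff <- function(series, window = 10, votes = 6) {
  if (nrow(series) < window + 1) {
    return(NA_real_)
  }
  wins <- embed(series$ratio, window + 1) # row i = ratios ending at i+window
  hit <- which(rowSums(wins > 1) >= votes)
  if (length(hit) == 0) {
    return(NA_real_)
  }
  series$length[hit[1] + window] - window / 2
}
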