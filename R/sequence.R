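#' @keywords internal
DNA_BASES <- c("A", "C", "G", "T")

#' Validate and normalize a raw DNA sequence
#'
#' Strips whitespace, upper-cases, and enforces the strict `{A,C,G,T}`
#' alphabet the codec is defined over. Ambiguity codes (`N`, IUPAC symbols),
#' gaps and `U` are rejected rather than silently dropped: a codec must not
#' lose bases.
#'
#' @param raw A character scalar containing the sequence (whitespace,
#'   including internal line breaks, is removed).
#' @return A single uppercase string over `A`, `C`, `G`, `T`.
#' @examples
#' normalize_sequence("acgt")
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop_ddqr("ddqr_invalid_base_error", "sequence must be a single character string")
  }
  seq <- toupper(gsub("[[:space:]]+", "", raw))
  if (nchar(seq) == 0L) {
    stop_ddqr("ddqr_empty_sequence_error", "empty sequence")
  }
  bad <- regexpr("[^ACGT]", seq)
  if (bad != -1L) {
    stop_ddqr(
      "ddqr_invalid_base_error",
      sprintf(
        "invalid base '%s' at position %d (alphabet is A, C, G, T)",
        substr(seq, bad, bad), bad
      ),
      base = substr(seq, bad, bad), position = as.integer(bad)
    )
  }
  seq
}

#' Count base frequencies of a sequence
#'
#' @param seq A normalized sequence (see [normalize_sequence()]).
#' @return A list with `counts` (named integer vector over A, C, G, T,
#'   zeros included) and `freqs` (`counts / length`), plus `length`.
#' @examples
#' count_frequencies("AAAT")$freqs
#' @export
count_frequencies <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  counts <- vapply(DNA_BASES, function(b) sum(chars == b), integer(1L))
  n <- length(chars)
  stopifnot(sum(counts) == n)
  list(counts = counts, freqs = counts / n, length = n)
}

#' Rank bases by descending frequency
#'
#' Returns the permutation (nt1, nt2, nt3, nt4) of `A,C,G,T` ordered by
#' descending count. Ties are broken alphabetically (A < C < G < T) so the
#' ranking — and hence the encoded bitstream — is deterministic.
#'
#' @param freqs A frequency table from [count_frequencies()], or a named
#'   count vector over the four bases.
#' @return Character vector of length 4: the bases ranked nt1..nt4.
#' @examples
#' rank_bases(count_frequencies("AAAT"))
#' @export
rank_bases <- function(freqs) {
  counts <- if (is.list(freqs)) freqs$counts else freqs
  counts <- counts[DNA_BASES] # alphabetical tie-break via stable sort
  DNA_BASES[order(-counts)]
}
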