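# FASTA ingestion, barcode length filters, and per-dataset compression
# statistics.

#' Read sequence records from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; records are
#' upper-cased and checked against the strict `{A,C,G,T}` codec alphabet.
#' Records containing other characters (N, IUPAC ambiguity codes, gaps) are
#' flagged in the `valid` column and, by default, kept so the caller can
#' decide; `on_invalid = "drop"` removes them, `"error"` aborts.
#'
#' @param path FASTA file path.
#' @param on_invalid One of `"flag"` (default), `"drop"`, `"error"`.
#' @return A data frame with columns `id`, `seq`, `length`, `valid`,
#'   `source_file`. Duplicate ids are disambiguated with `-1`, `-2`, ...
#'   suffixes.
#' @export
read_fasta <- function(path, on_invalid = c("flag", "drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) {
    stop_ddqr("ddqr_parse_error", sprintf("file not found: %s", path))
  }
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(!grepl("^[[:space:]]*$", first))
  if (length(nonblank) > 0L && !startsWith(trimws(first[nonblank[1L]]), ">")) {
    stop_ddqr(
      "ddqr_parse_error",
      sprintf("malformed FASTA: sequence before first header at line %d", nonblank[1L]),
      line = nonblank[1L]
    )
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop_ddqr("ddqr_parse_error", sprintf("malformed FASTA: %s", conditionMessage(e)))
    }
  )
  ids <- sub("[[:space:]].*$", "", names(set))
  ids[ids == ""] <- "unnamed"
  dup <- ave(seq_along(ids), ids, FUN = seq_along)
  ids[dup > 1L] <- paste0(ids[dup > 1L], "-", dup[dup > 1L] - 1L)
  seqs <- toupper(as.character(set))
  valid <- !grepl("[^ACGT]", seqs)
  if (on_invalid == "error" && any(!valid)) {
    stop_ddqr(
      "ddqr_invalid_base_error",
      sprintf(
        "%d record(s) contain characters outside {A,C,G,T}; first: %s",
        sum(!valid), ids[which(!valid)[1L]]
      )
    )
  }
  out <- data.frame(
    id = ids, seq = unname(seqs), length = nchar(seqs),
    valid = valid, source_file = path,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (on_invalid == "drop") out <- out[out$valid, , drop = FALSE]
  out
}

#' Write sequence records to a FASTA file
#'
#' @param records Data frame with `id` and `seq` columns (as from
#'   [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Length filter for barcode datasets
#'
#' Presets follow the marker pre-processing conventions: `"plant"` keeps
#' 150--600 bp (rbcL, matK, psbA-trnH, ITS2), `"coi"` keeps 100--700 bp.
#' Bounds are inclusive.
#'
#' @param preset `"plant"`, `"coi"`, or `NULL` when giving explicit bounds.
#' @param min_bp,max_bp Explicit inclusive bounds.
#' @return A `ddqr_length_filter` list with `min_bp`, `max_bp`.
#' @export
length_filter <- function(preset = NULL, min_bp = NULL, max_bp = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("plant", "coi"))
    bounds <- switch(preset, plant = c(150L, 600L), coi = c(100L, 700L))
    min_bp <- bounds[1L]
    max_bp <- bounds[2L]
  }
  stopifnot(is.numeric(min_bp), is.numeric(max_bp), min_bp <= max_bp)
  structure(
    list(min_bp = as.integer(min_bp), max_bp = as.integer(max_bp)),
    class = "ddqr_length_filter"
  )
}

#' Filter records by sequence length
#'
#' Keeps records with `min_bp <= length <= max_bp` (inclusive), preserving
#' order, and reports the kept/removed counts as a message.
#'
#' @param records Data frame from [read_fasta()].
#' @param filter A [length_filter()] or a preset name (`"plant"`, `"coi"`).
#' @return The filtered data frame.
#' @export
apply_length_filter <- function(records, filter) {
  if (is.character(filter)) filter <- length_filter(preset = filter)
  stopifnot(inherits(filter, "ddqr_length_filter"))
  keep <- records$length >= filter$min_bp & records$length <= filter$max_bp
  message(sprintf(
    "length filter [%d, %d]: kept %d, removed %d",
    filter$min_bp, filter$max_bp, sum(keep), sum(!keep)
  ))
  records[keep, , drop = FALSE]
}

#' Per-dataset compression statistics
#'
#' Encodes every valid record and summarizes the dataset: record count, mean
#' length, mean compression rate, and a rate histogram (bins of width 0.005
#' over `[0.15, 0.40]` plus underflow/overflow bins). Records flagged
#' invalid (ambiguous bases) are excluded from the statistics and counted in
#' `n_excluded`.
#'
#' @param records Data frame from [read_fasta()] (a `valid` column is
#'   honoured when present).
#' @param profile Header profile for the rate; default `"paper"`, the
#'   variant the published per-marker averages correspond to.
#' @return A list of class `ddqr_dataset_stats`: `n_sequences`,
#'   `n_excluded`, `mean_length`, `mean_rate`, `rates`, `histogram`
#'   (data frame `bin_low`, `bin_high`, `count`).
#' @export
dataset_stats <- function(records, profile = c("paper", "robust")) {
  profile <- match.arg(profile)
  if (!is.null(records$valid)) {
    n_excluded <- sum(!records$valid)
    records <- records[records$valid, , drop = FALSE]
  } else {
    n_excluded <- 0L
  }
  if (nrow(records) == 0L) {
    stop_ddqr("ddqr_empty_sequence_error", "no valid records to summarize")
  }
  rates <- vapply(records$seq, compression_rate,
    numeric(1L),
    profile = profile, USE.NAMES = FALSE
  )
  breaks <- c(-Inf, seq(0.15, 0.40, by = 0.005), Inf)
  counts <- as.integer(table(cut(rates, breaks = breaks, right = FALSE)))
  hist <- data.frame(
    bin_low = breaks[-length(breaks)],
    bin_high = breaks[-1L],
    count = counts
  )
  structure(
    list(
      n_sequences = nrow(records),
      n_excluded = n_excluded,
      mean_length = mean(nchar(records$seq)),
      mean_rate = mean(rates),
      rates = rates,
      histogram = hist,
      profile = profile
    ),
    class = "ddqr_dataset_stats"
  )
}

#' @export
print.ddqr_dataset_stats <- function(x, ...) {
  cat(sprintf(
    "DDQR dataset statistics (%s profile)\n  sequences: %d (excluded: %d)\n  mean length: %.1f bp\n  mean compression rate: %.4f (%.2f%%)\n",
    x$profile, x$n_sequences, x$n_excluded, x$mean_length,
    x$mean_rate, 100 * x$mean_rate
  ))
  invisible(x)
}
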