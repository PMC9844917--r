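# Simulation study: random sequences with a controlled dominant-base
# proportion, compression-rate sweeps over length x composition, ratio
# series against a comparator compressor, and the sliding-window detector
# for the length cutoff at which the comparator overtakes the dynamic codec.

#' Generate a random DNA sequence with a dominant base
#'
#' The dominant base receives probability `dominant_fraction`; the remaining
#' mass is split over the other three bases by a flat Dirichlet draw on the
#' scaled 3-simplex ("the remaining proportions are generated randomly"),
#' conditioned on the dominant base actually being the modal base: draws in
#' which a minor proportion exceeds `dominant_fraction` are rejected and
#' redrawn. At the `dominant_fraction = 0.25` boundary the only admissible
#' composition is the uniform one, which is used exactly. Bases are then
#' sampled independently per position. With `exact_counts = TRUE` the drawn
#' proportions are converted to integer counts (largest-remainder rounding)
#' and the sequence is a random permutation of exactly those counts.
#'
#' @param length Sequence length in bases (>= 1).
#' @param dominant_fraction Proportion of the dominant base, in
#'   `[0.25, 1]` (a maximum frequency below 1/4 is impossible over four
#'   symbols).
#' @param dominant_base The base given the dominant proportion (default
#'   `"A"`).
#' @param exact_counts Sample exact category counts instead of i.i.d.
#'   positions.
#' @return A sequence string. Uses the current RNG state; seed via
#'   [set.seed()] or the `seed` arguments of the sweep functions.
#' @export
generate_sequence <- function(length, dominant_fraction, dominant_base = "A",
                              exact_counts = FALSE) {
  if (length < 1L) {
    stop_ddqr("ddqr_empty_sequence_error", "length must be >= 1")
  }
  if (dominant_fraction < 0.25 || dominant_fraction > 1) {
    stop_ddqr(
      "ddqr_invalid_base_error",
      "dominant_fraction must be in [0.25, 1]"
    )
  }
  others <- setdiff(DNA_BASES, dominant_base)
  if (dominant_fraction <= 0.25 + 1e-12) {
    minors <- rep(0.25, 3L) # boundary: uniform is the only admissible mix
  } else {
    # flat Dirichlet(1,1,1) via normalized exponentials, conditioned on the
    # dominant base staying modal
    repeat {
      w <- stats::rexp(3L)
      minors <- (1 - dominant_fraction) * w / sum(w)
      if (all(minors <= dominant_fraction)) break
    }
  }
  probs <- c(dominant_fraction, minors)
  bases <- c(dominant_base, others)
  if (exact_counts) {
    target <- probs * length
    counts <- floor(target)
    short <- length - sum(counts)
    if (short > 0L) {
      counts[order(target - floor(target), decreasing = TRUE)[seq_len(short)]] <-
        counts[order(target - floor(target), decreasing = TRUE)[seq_len(short)]] + 1L
    }
    paste(sample(rep.int(bases, counts)), collapse = "")
  } else {
    paste(sample(bases, length, replace = TRUE, prob = probs), collapse = "")
  }
}

#' Specify a simulation sweep
#'
#' @param lengths Integer vector of sequence lengths.
#' @param dominant_fractions Numeric vector of dominant-base proportions in
#'   `[0.25, 1]` (the study grid is 25\% to 95\% in 1\% steps).
#' @param dominant_base Dominant base (default `"A"`).
#' @param replicates Sequences per (length, composition) cell (default 500).
#' @param seed RNG seed making the sweep reproducible.
#' @return A `ddqr_simulation_spec` list.
#' @export
simulation_spec <- function(lengths, dominant_fractions = 0.25,
                            dominant_base = "A", replicates = 500L,
                            seed = 1L) {
  stopifnot(
    all(lengths >= 1L), replicates >= 1L,
    all(dominant_fractions >= 0.25), all(dominant_fractions <= 1)
  )
  structure(
    list(
      lengths = as.integer(lengths),
      dominant_fractions = dominant_fractions,
      dominant_base = dominant_base,
      replicates = as.integer(replicates),
      seed = as.integer(seed)
    ),
    class = "ddqr_simulation_spec"
  )
}

#' Run a compression-rate sweep
#'
#' For every (length, dominant fraction) cell, generates `replicates` random
#' sequences, encodes each, and tabulates the mean and standard deviation of
#' the compression rate. Deterministic given the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @param profile Header profile for the rate ([compression_rate()]);
#'   defaults to `"paper"`, which the published mean rates correspond to.
#' @return A data frame with columns `length`, `dominant_fraction`, `n`,
#'   `mean_rate`, `sd_rate`.
#' @examples
#' run_sweep(simulation_spec(lengths = 200, replicates = 20, seed = 7))
#' @export
run_sweep <- function(spec, profile = c("paper", "robust")) {
  profile <- match.arg(profile)
  stopifnot(inherits(spec, "ddqr_simulation_spec"))
  set.seed(spec$seed)
  grid <- expand.grid(
    length = spec$lengths, dominant_fraction = spec$dominant_fractions,
    KEEP.OUT.ATTRS = FALSE
  )
  res <- lapply(seq_len(nrow(grid)), function(i) {
    rates <- vapply(seq_len(spec$replicates), function(r) {
      seq <- generate_sequence(
        grid$length[i], grid$dominant_fraction[i], spec$dominant_base
      )
      compression_rate(seq, profile = profile)
    }, numeric(1L))
    c(mean_rate = mean(rates), sd_rate = stats::sd(rates))
  })
  res <- do.call(rbind, res)
  data.frame(
    length = grid$length,
    dominant_fraction = grid$dominant_fraction,
    n = spec$replicates,
    mean_rate = res[, "mean_rate"],
    sd_rate = res[, "sd_rate"]
  )
}

#' Ratio of mean compression rates against a comparator
#'
#' For each length in the spec, computes the mean DDQR compression rate and
#' the mean rate of a comparator compressor on the same sequences, and
#' returns their ratio series. The comparator is a plug-in function mapping
#' a sequence to its compressed size in output characters (an external tool
#' such as GeCo3 can be wrapped as a subprocess adapter); its rate is
#' `size / length`.
#'
#' @param spec A [simulation_spec()]; its `dominant_fractions` must have
#'   length 1 for a single series.
#' @param comparator `function(seq) -> size` in characters.
#' @param profile Header profile for the DDQR rate.
#' @return A data frame with columns `length`, `ratio` (DDQR / comparator),
#'   `mean_rate_ddqr`, `mean_rate_comparator`. Lengths where the comparator
#'   failed on every replicate are dropped with a warning.
#' @export
ratio_series <- function(spec, comparator, profile = c("paper", "robust")) {
  profile <- match.arg(profile)
  stopifnot(inherits(spec, "ddqr_simulation_spec"), is.function(comparator))
  set.seed(spec$seed)
  rows <- lapply(spec$lengths, function(L) {
    ddqr_rates <- numeric(spec$replicates)
    comp_rates <- rep(NA_real_, spec$replicates)
    for (r in seq_len(spec$replicates)) {
      seq <- generate_sequence(L, spec$dominant_fractions[1L], spec$dominant_base)
      ddqr_rates[r] <- compression_rate(seq, profile = profile)
      size <- tryCatch(comparator(seq), error = function(e) NA_real_)
      if (!is.na(size)) comp_rates[r] <- size / L
    }
    if (all(is.na(comp_rates))) {
      warning(sprintf("comparator failed at length %d; cell skipped", L))
      return(NULL)
    }
    data.frame(
      length = L,
      ratio = mean(ddqr_rates) / mean(comp_rates, na.rm = TRUE),
      mean_rate_ddqr = mean(ddqr_rates),
      mean_rate_comparator = mean(comp_rates, na.rm = TRUE)
    )
  })
  do.call(rbind, rows)
}

#' Detect the comparator cutoff length in a ratio series
#'
#' Slides an 11-point window (lengths `i - 10` to `i`) over a consecutive
#' ratio series; at the first window in which at least 6 of the 11 ratios
#' exceed 1, the cutoff is declared at length `i - 5` (the window center).
#' Returns an undefined cutoff when the rule never triggers.
#'
#' @param series Data frame with columns `length` (consecutive integers,
#'   step 1) and `ratio`, e.g. from [ratio_series()].
#' @param window Window span below the current length (default 10, giving
#'   11 ratios per window).
#' @param votes Number of ratios that must exceed 1 (default 6).
#' @return A list with `cutoff_length` (`NA` when never triggered),
#'   `triggered`, `window`, `votes`.
#' @examples
#' s <- data.frame(length = 1:200, ratio = c(rep(0.9, 99), rep(1.1, 101)))
#' detect_cutoff(s)$cutoff_length # 100
#' @export
detect_cutoff <- function(series, window = 10L, votes = 6L) {
  stopifnot(all(c("length", "ratio") %in% names(series)))
  if (nrow(series) < window + 1L) {
    stop_ddqr(
      "ddqr_insufficient_data_error",
      sprintf("need at least %d consecutive points, got %d", window + 1L, nrow(series))
    )
  }
  if (any(diff(series$length) != 1L)) {
    stop_ddqr("ddqr_insufficient_data_error", "series lengths must be consecutive with step 1")
  }
  above <- series$ratio > 1
  for (i in seq.int(window + 1L, nrow(series))) {
    if (sum(above[(i - window):i]) >= votes) {
      return(list(
        cutoff_length = series$length[i] - window / 2,
        triggered = TRUE, window = window, votes = votes
      ))
    }
  }
  list(cutoff_length = NA_real_, triggered = FALSE, window = window, votes = votes)
}
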