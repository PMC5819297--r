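#' Read-cleaning parameters
#'
#' Defaults mirror the usual sliding-window trimming recipe for short MiSeq
#' reads: a 4-base window, a mean-quality floor of Q25, and a 30-base minimum
#' length after trimming. Adapter handling is exact-substring matching on the
#' untrimmed read (default: no adapters).
#'
#' @param window Window width in bases.
#' @param min_mean_q Minimum mean phred quality per window.
#' @param min_len Minimum read length after trimming; shorter reads are
#'   dropped.
#' @param adapters Character vector of adapter sequences; any read containing
#'   one verbatim is dropped.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(window = 4L, min_mean_q = 25, min_len = 30L,
                      adapters = character()) {
  stopifnot_scalar_count(window, "window")
  stopifnot_scalar_count(min_len, "min_len")
  structure(list(window = as.integer(window), min_mean_q = min_mean_q,
                 min_len = as.integer(min_len),
                 adapters = clean_dna(adapters, "adapter")),
            class = "qc_params")
}

# 5'->3' leading-edge scan: number of bases kept before the first window
# (1-based starts 1..L-w+1) whose mean quality is strictly below `minq`.
# Reads shorter than the window are left untouched.
trim_keep_len <- function(q, window, minq) {
  L <- length(q)
  if (L < window) return(L)
  cs <- cumsum(q)
  means <- (cs[window:L] - c(0, cs)[1:(L - window + 1L)]) / window
  first_bad <- which(means < minq)[1]
  if (is.na(first_bad)) L else first_bad - 1L
}

#' Sliding-window quality trimming
#'
#' Scans each read 5' to 3' with a window of `params$window` bases and cuts
#' the read immediately before the start of the first window whose mean
#' quality falls below `params$min_mean_q`. Reads containing an adapter as an
#' exact substring, and reads left shorter than `params$min_len`, are marked
#' dropped. Trimming is idempotent and output reads are always prefixes of
#' their inputs.
#'
#' @param reads Read tibble (`id`, `seq`, `qual`).
#' @param params A [qc_params()] object.
#' @return The input tibble with `seq`/`qual` trimmed and two extra columns:
#'   `kept` (logical) and `drop_reason` (`NA`, `"short"` or `"adapter"`).
#' @export
sliding_window_trim <- function(reads, params = qc_params()) {
  reads <- as_tibble(reads)
  n <- nrow(reads)
  if (n == 0L) {
    return(mutate(reads, kept = logical(0), drop_reason = character(0)))
  }
  quals <- lapply(reads$qual, function(s) utf8ToInt(s) - 33L)
  keep_len <- vapply(quals, trim_keep_len, integer(1),
                     window = params$window, minq = params$min_mean_q)
  has_adapter <- rep(FALSE, n)
  for (ad in params$adapters) {
    has_adapter <- has_adapter | grepl(ad, reads$seq, fixed = TRUE)
  }
  out <- reads
  out$seq <- substr(reads$seq, 1L, keep_len)
  out$qual <- substr(reads$qual, 1L, keep_len)
  out$kept <- !has_adapter & keep_len >= params$min_len
  out$drop_reason <- dplyr::case_when(
    has_adapter ~ "adapter",
    keep_len < params$min_len ~ "short",
    TRUE ~ NA_character_
  )
  out
}

#' Clean a read set
#'
#' Applies [sliding_window_trim()] to every read and keeps the survivors.
#' The QC statistics are attached as the `"qc_stats"` attribute and
#' retrievable with [qc_stats()].
#'
#' @inheritParams sliding_window_trim
#' @return Tibble of kept (trimmed) reads with attribute `qc_stats`.
#' @export
clean_readset <- function(reads, params = qc_params()) {
  trimmed <- sliding_window_trim(reads, params)
  kept <- trimmed[trimmed$kept, c("id", "seq", "qual")]
  n_in <- nrow(trimmed)
  stats <- tibble(
    n_input = n_in,
    n_kept = nrow(kept),
    n_dropped_short = sum(trimmed$drop_reason %in% "short"),
    n_dropped_adapter = sum(trimmed$drop_reason %in% "adapter"),
    fraction_removed = if (n_in == 0L) 0 else 100 * (n_in - nrow(kept)) / n_in
  )
  attr(kept, "qc_stats") <- stats
  kept
}

#' @rdname clean_readset
#' @param x A tibble returned by [clean_readset()].
#' @export
qc_stats <- function(x) attr(x, "qc_stats")
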