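#' Per-nucleotide read coverage along a consensus
#'
#' Aligns every read against a single consensus record and increments the
#' coverage over the aligned reference span of each read whose best local
#' alignment passes the scheme thresholds. The raw (unnormalized) profile is
#' returned; the sum of its values equals the total number of aligned
#' reference bases. For tandem records coverage is folded onto the monomer.
#'
#' @param reads Read tibble.
#' @param consensus One-row library record (e.g. `lib[lib$name == "L1", ]`).
#' @param scheme A [scoring_scheme()].
#' @param exhaustive Disable the k-mer seed prefilter.
#' @return A `coverage_profile` tibble (`position`, `coverage`) with
#'   attributes `consensus_name`, `n_reads_total`, `n_aligned`, `normalized`.
#' @export
profile_coverage <- function(reads, consensus, scheme = scoring_scheme(),
                             exhaustive = FALSE) {
  if (nrow(consensus) != 1L) abort("`consensus` must be a single record")
  if (!nzchar(consensus$seq)) abort("empty consensus")
  reads <- as_tibble(reads)
  out_len <- if (isTRUE(consensus$is_tandem)) {
    consensus$monomer_len
  } else {
    nchar(consensus$seq)
  }
  values <- numeric(out_len)
  n_aligned <- 0L
  if (nrow(reads) > 0L) {
    read_len <- max(nchar(reads$seq))
    ref <- reference_seq(consensus, read_len = read_len)
    hits <- .classify_cpp(reads$seq, ref, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend,
                          scheme$min_score, scheme$min_aln_len,
                          11L, 8L, isTRUE(exhaustive))
    n_aligned <- nrow(hits)
    if (n_aligned > 0L) {
      cov <- IRanges::coverage(
        IRanges::IRanges(start = hits$ref_start, end = hits$ref_end),
        width = nchar(ref))
      cov <- as.numeric(cov)
      if (isTRUE(consensus$is_tandem)) {
        pos <- (seq_along(cov) - 1L) %% out_len + 1L
        acc <- rowsum(cov, pos)  # groups sorted numerically
        values <- numeric(out_len)
        values[as.integer(rownames(acc))] <- acc[, 1]
      } else {
        values <- cov[seq_len(out_len)]
      }
    }
  }
  new_coverage_profile(values, consensus$name, nrow(reads), n_aligned)
}

# Low-level constructor (also used to build profiles directly in tests).
new_coverage_profile <- function(values, consensus_name, n_reads_total,
                                 n_aligned, normalized = FALSE) {
  structure(
    tibble(position = seq_along(values), coverage = as.numeric(values)),
    consensus_name = consensus_name,
    n_reads_total = n_reads_total,
    n_aligned = n_aligned,
    normalized = normalized,
    class = c("coverage_profile", class(tibble())))
}

#' Normalize a coverage profile by dataset size
#'
#' Scales the profile to reads-per-`per` of the originating dataset
#' (reads-per-million by default), so profiles from datasets of different
#' depth are comparable. Normalizing an already normalized profile is an
#' error.
#'
#' @param p A `coverage_profile`.
#' @param per Scale denominator (default 1e6 reads).
#' @param by `"total_reads"` (default) scales by the dataset size the
#'   profile was built from; `"aligned_reads"` by the number of reads that
#'   aligned to this consensus.
#' @return The scaled `coverage_profile` with `normalized = TRUE`.
#' @export
normalize_profile <- function(p, per = 1e6, by = c("total_reads",
                                                   "aligned_reads")) {
  by <- match.arg(by)
  if (isTRUE(attr(p, "normalized"))) abort("profile is already normalized")
  denom <- if (by == "total_reads") attr(p, "n_reads_total") else attr(p, "n_aligned")
  if (is.null(denom) || denom == 0) abort("cannot normalize: zero reads")
  p$coverage <- p$coverage * (per / denom)
  attr(p, "normalized") <- TRUE
  p
}

# Centered moving average with shrinking windows at the profile edges.
smooth_profile <- function(values, window) {
  L <- length(values)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(values))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call enriched sub-element segments in a coverage profile
#'
#' Smooths the profile with a centered moving average, marks positions where
#' the smoothed coverage reaches `fold_threshold` times the profile median,
#' merges marked runs separated by less than `smooth_window` positions, and
#' reports merged runs of at least `min_segment_len` bases. Calls are
#' invariant under global scaling of the profile. An all-zero-median profile
#' yields no calls.
#'
#' @param p A `coverage_profile`.
#' @param smooth_window Moving-average window (positions).
#' @param fold_threshold Enrichment threshold over the profile median.
#' @param min_segment_len Minimum reported segment length (positions).
#' @return Tibble of segments: `start`, `end` (1-based inclusive), `width`,
#'   `mean_fold`.
#' @export
detect_enriched_segments <- function(p, smooth_window = 101L,
                                     fold_threshold = 3.0,
                                     min_segment_len = 200L) {
  empty <- tibble(start = integer(), end = integer(), width = integer(),
                  mean_fold = numeric())
  if (nrow(p) <= smooth_window) {
    abort("profile must be longer than `smooth_window`")
  }
  med <- median(p$coverage)
  if (med <= 0) return(empty)
  sm <- smooth_profile(p$coverage, smooth_window)
  marked <- sm >= fold_threshold * med
  if (!any(marked)) return(empty)
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  # merge runs separated by short gaps
  merged <- runs[1, ]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap < smooth_window) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- bind_rows(merged, runs[i, ])
      }
    }
  }
  merged$width <- merged$end - merged$start + 1L
  merged <- merged[merged$width >= min_segment_len, ]
  merged$mean_fold <- vapply(seq_len(nrow(merged)), function(i) {
    mean(sm[merged$start[i]:merged$end[i]]) / med
  }, numeric(1))
  merged
}
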