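#' Local alignment scoring scheme
#'
#' Affine-gap Smith-Waterman parameters used by the classifier, the coverage
#' profiler and the contig annotators. A gap of length L costs
#' `gap_open + L * gap_extend`. Alignments scoring below `min_score` or
#' spanning fewer than `min_aln_len` columns are treated as no hit.
#'
#' @param match,mismatch,gap_open,gap_extend Integer scores; `match` must be
#'   positive, the others negative.
#' @param min_score Minimum reportable alignment score.
#' @param min_aln_len Minimum alignment length in columns.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L, min_score = 40L,
                           min_aln_len = 20L) {
  if (match <= 0 || mismatch >= 0) abort("need match > 0 > mismatch")
  if (min_score <= 0) abort("min_score must be positive")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score = as.integer(min_score),
                 min_aln_len = as.integer(min_aln_len)),
            class = "scoring_scheme")
}

#' Best local alignment of a query against a reference
#'
#' Runs exhaustive affine-gap Smith-Waterman on both query strands and
#' returns the better one. Coordinates are 1-based inclusive; reverse-strand
#' hits report reference coordinates on the forward reference.
#'
#' @param query,reference DNA strings.
#' @param scheme A [scoring_scheme()].
#' @return A one-row tibble (`score`, `q_start`, `q_end`, `r_start`, `r_end`,
#'   `strand`, `matches`, `aln_len`, `identity`), or a zero-row tibble when
#'   no alignment reaches `min_score` and `min_aln_len`.
#' @export
align_local <- function(query, reference, scheme = scoring_scheme()) {
  if (!nzchar(query) || !nzchar(reference)) abort("empty sequence")
  query <- clean_dna(query, "query")
  reference <- clean_dna(reference, "reference")
  fw <- .sw_align_cpp(query, reference, scheme$match, scheme$mismatch,
                      scheme$gap_open, scheme$gap_extend)
  rv <- .sw_align_cpp(revcomp(query), reference, scheme$match, scheme$mismatch,
                      scheme$gap_open, scheme$gap_extend)
  use_fw <- fw[["score"]] >= rv[["score"]]
  a <- if (use_fw) fw else rv
  out <- tibble(
    score = a[["score"]], q_start = a[["q_start"]], q_end = a[["q_end"]],
    r_start = a[["r_start"]], r_end = a[["r_end"]],
    strand = if (use_fw) "+" else "-",
    matches = a[["matches"]], aln_len = a[["aln_len"]],
    identity = ifelse(a[["aln_len"]] > 0, 100 * a[["matches"]] / a[["aln_len"]],
                      NA_real_)
  )
  out[out$score >= scheme$min_score & out$aln_len >= scheme$min_aln_len, ]
}

# Karlin-Altschul lambda for the ungapped scoring model under a uniform
# base background; solved at runtime from the scheme.
karlin_lambda <- function(scheme) {
  f <- function(l) {
    0.25 * exp(l * scheme$match) + 0.75 * exp(l * scheme$mismatch) - 1
  }
  uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

# Ungapped Karlin-Altschul expectation for a score over an m x n search
# space. K is a standard ballpark constant; both screen thresholds that
# consume these values are exposed as arguments.
karlin_evalue <- function(score, m, n, scheme, K = 0.1) {
  K * as.numeric(m) * as.numeric(n) * exp(-karlin_lambda(scheme) * score)
}
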