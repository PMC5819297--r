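#' Large tandem-repeat criteria
#'
#' The large-TR definition used throughout: monomers tandemly arranged
#' without inserts, monomer length below `max_monomer_len` (2 kb) and array
#' span above `min_array_len` (3 kb). `max_insert_gap` operationalizes
#' "without inserts" as the largest tolerated gap between consecutive
#' monomer hits; `identity_threshold` is the minimum percent identity of a
#' monomer hit against its consensus.
#'
#' @param max_monomer_len,min_array_len,max_insert_gap Lengths in bases.
#' @param identity_threshold Percent identity in \[0, 100\].
#' @return A list of class `tr_criteria`.
#' @export
tr_criteria <- function(max_monomer_len = 2000L, min_array_len = 3000L,
                        max_insert_gap = 50L, identity_threshold = 75) {
  structure(list(max_monomer_len = max_monomer_len,
                 min_array_len = min_array_len,
                 max_insert_gap = max_insert_gap,
                 identity_threshold = identity_threshold),
            class = "tr_criteria")
}

#' Non-overlapping monomer hits in a contig
#'
#' Finds all non-overlapping local alignments of a tandem monomer against a
#' contig on both strands, greedily by descending score (each hit's span is
#' masked before searching for the next). Hits below the scheme score floor
#' or the identity threshold are not reported.
#'
#' @param contig DNA string.
#' @param monomer One-row tandem library record.
#' @param scheme A [scoring_scheme()].
#' @param criteria A [tr_criteria()].
#' @param max_hits Safety cap on the number of hits retrieved.
#' @return Tibble of hits sorted by `start`: `start`, `end` (1-based
#'   inclusive), `strand`, `score`, `identity`, `hit_len`.
#' @export
find_monomer_hits <- function(contig, monomer, scheme = scoring_scheme(),
                              criteria = tr_criteria(), max_hits = 10000L) {
  if (!isTRUE(monomer$is_tandem)) {
    abort(sprintf("record '%s' is not tandem", monomer$name))
  }
  hits <- as_tibble(.find_hits_cpp(
    monomer$seq, clean_dna(contig, "contig"),
    scheme$match, scheme$mismatch, scheme$gap_open, scheme$gap_extend,
    scheme$min_score, max_hits))
  hits$identity <- ifelse(hits$aln_len > 0, 100 * hits$matches / hits$aln_len,
                          0)
  hits$hit_len <- hits$end - hits$start + 1L
  hits <- hits[hits$identity >= criteria$identity_threshold &
                 hits$aln_len >= scheme$min_aln_len, ]
  arrange(hits[, c("start", "end", "strand", "score", "identity", "hit_len")],
          .data$start)
}

#' Chain monomer hits into tandem arrays
#'
#' Consecutive same-strand hits whose inter-hit gap does not exceed
#' `criteria$max_insert_gap` are chained into one array. `n_monomers` counts
#' complete monomer copies (hits spanning at least 90% of the monomer);
#' partial trailing hits extend the span but are not counted. The
#' `meets_large_TR` flag applies the large-TR definition: monomer shorter
#' than `max_monomer_len` and array span above `min_array_len`. Arrays
#' without a single complete monomer are not reported.
#'
#' @param hits Hit tibble from [find_monomer_hits()], sorted by `start`.
#' @param criteria A [tr_criteria()].
#' @param monomer_len Monomer length in bases.
#' @return Tibble of arrays: `start`, `end`, `span`, `strand`, `n_monomers`,
#'   `n_hits`, `mean_identity`, `score`, `meets_large_TR`.
#' @export
chain_arrays <- function(hits, criteria = tr_criteria(), monomer_len) {
  empty <- tibble(start = integer(), end = integer(), span = integer(),
                  strand = character(), n_monomers = integer(),
                  n_hits = integer(), mean_identity = numeric(),
                  score = numeric(), meets_large_TR = logical())
  if (nrow(hits) == 0L) return(empty)
  if (is.unsorted(hits$start)) hits <- arrange(hits, .data$start)
  gap <- c(Inf, hits$start[-1] - hits$end[-nrow(hits)] - 1L)
  new_chain <- gap > criteria$max_insert_gap |
    c(TRUE, hits$strand[-1] != hits$strand[-nrow(hits)])
  chain_id <- cumsum(new_chain)
  out <- hits |>
    mutate(chain = chain_id,
           complete = .data$hit_len >= 0.9 * monomer_len) |>
    group_by(.data$chain) |>
    summarise(start = min(.data$start), end = max(.data$end),
              strand = .data$strand[1],
              n_monomers = sum(.data$complete),
              n_hits = dplyr::n(),
              mean_identity = mean(.data$identity),
              score = sum(.data$score), .groups = "drop") |>
    mutate(span = .data$end - .data$start + 1L,
           meets_large_TR = monomer_len < criteria$max_monomer_len &
             .data$span > criteria$min_array_len) |>
    filter(.data$n_monomers >= 1L) |>
    select("start", "end", "span", "strand", "n_monomers", "n_hits",
           "mean_identity", "score", "meets_large_TR")
  out
}

#' Detect tandem arrays of a family across contigs
#'
#' Convenience wrapper running [find_monomer_hits()] + [chain_arrays()] for
#' one tandem family over a set of contigs.
#'
#' @param contigs Tibble with `contig_id`, `seq`.
#' @param lib A [repeat_library()].
#' @param family Tandem family name present in `lib`.
#' @param criteria A [tr_criteria()].
#' @param scheme A [scoring_scheme()].
#' @return Tibble of arrays with `contig_id` and `family` prepended.
#' @export
find_tandem_arrays <- function(contigs, lib, family,
                               criteria = tr_criteria(),
                               scheme = scoring_scheme()) {
  rec <- lib[lib$name == family, ]
  if (nrow(rec) != 1L) abort(sprintf("unknown family '%s'", family))
  res <- purrr::map(seq_len(nrow(contigs)), function(i) {
    hits <- find_monomer_hits(contigs$seq[i], rec, scheme, criteria)
    arr <- chain_arrays(hits, criteria, rec$monomer_len)
    if (nrow(arr)) {
      bind_cols(tibble(contig_id = contigs$contig_id[i], family = family),
                arr)
    } else NULL
  }) |> list_rbind()
  if (!nrow(res)) {
    res <- bind_cols(tibble(contig_id = character(), family = character()),
                     chain_arrays(tibble(start = integer()), criteria,
                                  rec$monomer_len))
  }
  res
}
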