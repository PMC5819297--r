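#' Co-occurrence screen criteria
#'
#' A contig is called positive when it carries at least `min_monomers`
#' complete monomers of `tr_family` together with an ERV-derived fragment
#' longer than `min_te_fragment_len` bases (strictly greater). The
#' historical thresholds are one monomer for the major/minor satellites and
#' three for TRPC-21A, with a 400-bp fragment floor. `ltr_only = TRUE`
#' implements the narrower reading in which only LTR fragments qualify.
#'
#' @param tr_family Tandem family name.
#' @param min_monomers Minimum number of complete monomers.
#' @param min_te_fragment_len Fragment length floor in bases (exclusive).
#' @param ltr_only Only count `te_part == "LTR"` fragments as qualifying.
#' @return A list of class `screen_criteria`.
#' @export
screen_criteria <- function(tr_family, min_monomers = 1L,
                            min_te_fragment_len = 400L, ltr_only = FALSE) {
  structure(list(tr_family = tr_family,
                 min_monomers = as.integer(min_monomers),
                 min_te_fragment_len = min_te_fragment_len,
                 ltr_only = isTRUE(ltr_only)),
            class = "screen_criteria")
}

#' Annotate transposable-element fragments in a contig
#'
#' Aligns every library record with `te_part != "none"` against the contig
#' (both strands, non-overlapping per record, greedy best-score selection)
#' and applies the BLAST-style discard rule: a hit is discarded when its
#' e-value exceeds `max_evalue` AND its score is below `min_keep_score`.
#' E-values follow ungapped Karlin-Altschul statistics for the scoring
#' scheme with search space = record length x contig length. With
#' `score_only = TRUE` e-values are bypassed and hits below `min_keep_score`
#' are discarded.
#'
#' @param contig DNA string.
#' @param lib A [repeat_library()].
#' @param scheme A [scoring_scheme()].
#' @param max_evalue,min_keep_score Discard-rule thresholds.
#' @param score_only Bypass e-values.
#' @param contig_id Identifier used in the output.
#' @return Tibble of retained fragments in coordinate order: `contig_id`,
#'   `te_name`, `te_part`, `start`, `end`, `length`, `strand`, `score`,
#'   `evalue`.
#' @export
annotate_te <- function(contig, lib, scheme = scoring_scheme(),
                        max_evalue = 1e-10, min_keep_score = 100,
                        score_only = FALSE, contig_id = "contig") {
  contig <- clean_dna(contig, "contig")
  te <- lib[lib$te_part != "none", ]
  if (nrow(te) == 0L) abort("library contains no TE records")
  lambda <- karlin_lambda(scheme)
  frags <- purrr::map(seq_len(nrow(te)), function(i) {
    h <- as_tibble(.find_hits_cpp(
      te$seq[i], contig, scheme$match, scheme$mismatch, scheme$gap_open,
      scheme$gap_extend, scheme$min_score, 1000L))
    if (!nrow(h)) return(NULL)
    h$te_name <- te$name[i]
    h$te_part <- te$te_part[i]
    h$evalue <- 0.1 * nchar(te$seq[i]) * nchar(contig) *
      exp(-lambda * h$score)
    h
  }) |> list_rbind()
  out <- tibble(contig_id = character(), te_name = character(),
                te_part = character(), start = integer(), end = integer(),
                length = integer(), strand = character(), score = integer(),
                evalue = numeric())
  if (!nrow(frags)) return(out)
  keep <- if (score_only) {
    frags$score >= min_keep_score
  } else {
    !(frags$evalue > max_evalue & frags$score < min_keep_score)
  }
  frags <- frags[keep & frags$aln_len >= scheme$min_aln_len, ]
  if (!nrow(frags)) return(out)
  frags$contig_id <- contig_id
  frags$length <- frags$end - frags$start + 1L
  arrange(frags[, names(out)], .data$start)
}

# Paint features onto the contig; higher alignment score wins overlaps.
# Returns maximal annotated/unannotated intervals partitioning [1, len].
build_structure_map <- function(contig_len, features) {
  paint <- integer(contig_len)  # 0 = unannotated
  if (nrow(features)) {
    for (i in order(features$score)) {
      paint[features$start[i]:features$end[i]] <- i
    }
  }
  r <- rle(paint)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- r$values
  tibble(
    start = starts, end = ends,
    type = ifelse(idx == 0L, "unannotated", features$type[pmax(idx, 1L)]),
    feature = ifelse(idx == 0L, NA_character_,
                     features$feature[pmax(idx, 1L)]),
    strand = ifelse(idx == 0L, NA_character_,
                    features$strand[pmax(idx, 1L)])
  )
}

#' Screen one contig for tandem-repeat + ERV co-occurrence
#'
#' Runs the tandem-array finder for `criteria$tr_family` and the TE
#' annotator, then applies the positivity rule: total complete monomers of
#' the family at least `min_monomers` AND some retained TE fragment strictly
#' longer than `min_te_fragment_len`. The structure map partitions the whole
#' contig into maximal annotated/unannotated intervals (overlaps resolved by
#' alignment score). The positivity rule is re-checked on the assembled
#' result before returning.
#'
#' @param contig DNA string.
#' @param criteria A [screen_criteria()].
#' @param lib A [repeat_library()].
#' @param scheme A [scoring_scheme()].
#' @param trc A [tr_criteria()].
#' @param contig_id Identifier used in the output.
#' @param ... Passed to [annotate_te()].
#' @return One-row tibble: `contig_id`, `tr_family`, `positive`,
#'   `n_monomers`, `best_te_len`, plus list-columns `tr_evidence`,
#'   `te_evidence`, `structure_map`.
#' @export
screen_contig <- function(contig, criteria, lib, scheme = scoring_scheme(),
                          trc = tr_criteria(), contig_id = "contig", ...) {
  te <- annotate_te(contig, lib, scheme, contig_id = contig_id, ...)
  screen_with_te(contig, criteria, lib, te, scheme, trc, contig_id)
}

# Screen one contig against one criteria set, reusing precomputed TE
# fragments (screen_batch annotates each contig once across criteria).
screen_with_te <- function(contig, criteria, lib, te,
                           scheme = scoring_scheme(), trc = tr_criteria(),
                           contig_id = "contig") {
  rec <- lib[lib$name == criteria$tr_family, ]
  if (nrow(rec) != 1L) {
    abort(sprintf("tr_family '%s' not in library", criteria$tr_family))
  }
  hits <- find_monomer_hits(contig, rec, scheme, trc)
  arrays <- chain_arrays(hits, trc, rec$monomer_len)

  n_monomers <- sum(arrays$n_monomers)
  qual <- te
  if (criteria$ltr_only) qual <- qual[qual$te_part == "LTR", ]
  best_te_len <- if (nrow(qual)) max(qual$length) else 0L
  positive <- n_monomers >= criteria$min_monomers &&
    best_te_len > criteria$min_te_fragment_len

  feats <- bind_rows(
    if (nrow(arrays)) {
      tibble(start = arrays$start, end = arrays$end, strand = arrays$strand,
             score = arrays$score, type = "TR_array",
             feature = criteria$tr_family)
    },
    if (nrow(te)) {
      tibble(start = te$start, end = te$end, strand = te$strand,
             score = as.numeric(te$score),
             type = ifelse(te$te_part == "LTR", "TE_LTR", "TE_internal"),
             feature = te$te_name)
    }
  )
  if (is.null(feats)) {
    feats <- tibble(start = integer(), end = integer(), strand = character(),
                    score = numeric(), type = character(),
                    feature = character())
  }
  smap <- build_structure_map(nchar(contig), feats)

  # self-audit: the emitted verdict must satisfy the positivity invariant
  stopifnot(identical(positive,
                      n_monomers >= criteria$min_monomers &&
                        best_te_len > criteria$min_te_fragment_len))

  tibble(contig_id = contig_id, tr_family = criteria$tr_family,
         positive = positive, n_monomers = n_monomers,
         best_te_len = best_te_len,
         tr_evidence = list(arrays), te_evidence = list(te),
         structure_map = list(smap))
}

#' Screen a batch of contigs against one or more criteria
#'
#' @param contigs Tibble with `contig_id`, `seq` (duplicate ids are an
#'   error).
#' @param criteria_set A [screen_criteria()] or list of them.
#' @param lib A [repeat_library()].
#' @param scheme A [scoring_scheme()].
#' @param trc A [tr_criteria()].
#' @param ... Passed to [annotate_te()].
#' @return List with `results` (one row per contig x criteria) and `counts`
#'   (positive counts per criteria).
#' @export
screen_batch <- function(contigs, criteria_set, lib,
                         scheme = scoring_scheme(), trc = tr_criteria(),
                         ...) {
  if (inherits(criteria_set, "screen_criteria")) {
    criteria_set <- list(criteria_set)
  }
  if (anyDuplicated(contigs$contig_id)) {
    abort(paste("duplicate contig id(s):",
                paste(unique(contigs$contig_id[duplicated(contigs$contig_id)]),
                      collapse = ", ")))
  }
  results <- purrr::map(seq_len(nrow(contigs)), function(i) {
    te <- annotate_te(contigs$seq[i], lib, scheme,
                      contig_id = contigs$contig_id[i], ...)
    purrr::map(criteria_set, function(cr) {
      screen_with_te(contigs$seq[i], cr, lib, te, scheme, trc,
                     contig_id = contigs$contig_id[i])
    }) |> list_rbind()
  }) |> list_rbind()
  if (!nrow(results)) {
    results <- tibble(contig_id = character(), tr_family = character(),
                      positive = logical(), n_monomers = integer(),
                      best_te_len = integer())
  }
  counts <- results |>
    group_by(.data$tr_family) |>
    summarise(n_contigs = dplyr::n(), n_positive = sum(.data$positive),
              .groups = "drop")
  list(results = results, counts = counts)
}
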