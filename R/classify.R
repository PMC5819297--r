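#' Classify reads against a repeat library
#'
#' Every read is assigned to at most one repeat family by best local
#' alignment against every library record (tandem records via an expanded
#' head-to-tail reference so junction-spanning reads align contiguously).
#' Ties across families at the best score are broken by the library's
#' repclass priority order, then lexicographic family name, and flagged
#' `ambiguous`. Reads with no alignment passing `scheme$min_score` and
#' `scheme$min_aln_len` are left unassigned (`family = NA`).
#'
#' A k-mer seed prefilter (k = 11, with a k = 8 rescue pass for reads without
#' any 11-mer candidate) restricts alignment to seed-bounded reference
#' windows; it is lossless for any alignment containing at least one exact
#' seed. `exhaustive = TRUE` disables seeding and aligns every read against
#' every record in full.
#'
#' @param reads Read tibble (`id`, `seq`, ...), normally QC-cleaned.
#' @param lib A [repeat_library()].
#' @param scheme A [scoring_scheme()].
#' @param exhaustive Disable the seed prefilter.
#' @param read_len Nominal read length used to size expanded tandem
#'   references (defaults to the longest read present).
#' @return A tibble with one row per read: `read_id`, `family`, `subclass`,
#'   `repclass`, `te_part`, `score`, `ref_start`, `ref_end`, `strand`,
#'   `ambiguous`. Coordinates are 1-based inclusive; for tandem families
#'   `ref_start` is reduced modulo the monomer length (`ref_end` may run past
#'   it for junction-spanning reads).
#' @export
classify_reads <- function(reads, lib, scheme = scoring_scheme(),
                           exhaustive = FALSE, read_len = NULL) {
  if (!inherits(lib, "repeat_library") || nrow(lib) == 0L) {
    abort("`lib` must be a non-empty repeat_library")
  }
  reads <- as_tibble(reads)
  if (nrow(reads) == 0L) {
    return(tibble(read_id = character(), family = character(),
                  subclass = character(), repclass = character(),
                  te_part = character(), score = integer(),
                  ref_start = integer(), ref_end = integer(),
                  strand = character(), ambiguous = logical()))
  }
  read_len <- read_len %||% max(nchar(reads$seq))
  refs <- vapply(seq_len(nrow(lib)), function(i) {
    reference_seq(lib[i, ], read_len = read_len)
  }, character(1))

  hits <- as_tibble(.classify_cpp(
    reads$seq, refs, scheme$match, scheme$mismatch, scheme$gap_open,
    scheme$gap_extend, scheme$min_score, scheme$min_aln_len,
    11L, 8L, isTRUE(exhaustive)))

  prio <- priority_of(lib)
  if (nrow(hits) > 0L) {
    hits$family <- lib$name[hits$ref_idx]
    hits$repclass <- lib$repclass[hits$ref_idx]
    hits$prio_rank <- match(hits$repclass, prio)

    ord <- order(hits$read_idx, -hits$score, hits$prio_rank, hits$family,
                 method = "radix")  # byte order: locale-independent ties
    hits <- hits[ord, ]
    best <- !duplicated(hits$read_idx)
    nxt_same <- c(hits$read_idx[-1] == hits$read_idx[-nrow(hits)] &
                    hits$score[-1] == hits$score[-nrow(hits)], FALSE)
    assigned <- hits[best, ]
    assigned$ambiguous <- nxt_same[best]
  } else {
    assigned <- tibble(read_idx = integer(), ref_idx = integer(),
                       score = integer(), ref_start = integer(),
                       ref_end = integer(), strand = character(),
                       family = character(), ambiguous = logical())
  }

  # fold tandem coordinates back onto the monomer
  ml <- lib$monomer_len[assigned$ref_idx]
  tnd <- lib$is_tandem[assigned$ref_idx]
  span <- assigned$ref_end - assigned$ref_start
  new_start <- ifelse(tnd, (assigned$ref_start - 1L) %% ml + 1L,
                      assigned$ref_start)
  assigned$ref_start <- as.integer(new_start)
  assigned$ref_end <- as.integer(new_start + span)

  out <- tibble(read_idx = seq_len(nrow(reads)), read_id = reads$id)
  out <- left_join(out, assigned[, c("read_idx", "family", "score",
                                     "ref_start", "ref_end", "strand",
                                     "ambiguous")],
                   by = "read_idx")
  meta_idx <- match(out$family, lib$name)
  out$subclass <- lib$subclass[meta_idx]
  out$repclass <- lib$repclass[meta_idx]
  out$te_part <- lib$te_part[meta_idx]
  out$ambiguous <- ifelse(is.na(out$ambiguous), FALSE, out$ambiguous)
  out[, c("read_id", "family", "subclass", "repclass", "te_part", "score",
          "ref_start", "ref_end", "strand", "ambiguous")]
}

#' Classify a single read
#'
#' @inheritParams classify_reads
#' @param read One-row read tibble (or list with `id` and `seq`).
#' @return One-row assignment tibble; see [classify_reads()].
#' @export
classify_read <- function(read, lib, scheme = scoring_scheme(),
                          exhaustive = FALSE) {
  classify_reads(as_tibble(read[c("id", "seq")]), lib, scheme,
                 exhaustive = exhaustive)
}

#' Repeat composition of a read set
#'
#' Classifies all reads and aggregates assignments into a hierarchical
#' composition table: per-family rows, subclass and repclass roll-ups, an
#' `ERVAll` roll-up across the three ERV classes, an `All` total over every
#' assigned read and an `UNASSIGNED` row. Percentages use the total number
#' of (cleaned) input reads as denominator, unassigned reads included.
#'
#' @inheritParams classify_reads
#' @param assignments Optional precomputed result of [classify_reads()]; when
#'   supplied, `reads` may be missing and only its row count matters.
#' @return A `composition_table` tibble with columns `level` (`family`,
#'   `subclass`, `class`, `class_group`, `total`, `unassigned`), `repclass`,
#'   `subclass`, `family`, `count`, `percent`; attributes `n_total` and
#'   `zero_denominator`.
#' @export
quantify <- function(reads, lib, scheme = scoring_scheme(),
                     exhaustive = FALSE, assignments = NULL) {
  if (is.null(assignments)) {
    assignments <- classify_reads(reads, lib, scheme, exhaustive = exhaustive)
  }
  n_total <- nrow(assignments)
  pct <- function(k) if (n_total == 0L) 0 else 100 * k / n_total

  asg <- assignments[!is.na(assignments$family), ]
  fam <- asg |>
    count(.data$repclass, .data$subclass, .data$family, name = "count") |>
    mutate(level = "family")
  sub <- fam |>
    group_by(.data$repclass, .data$subclass) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(level = "subclass", family = NA_character_)
  cls <- fam |>
    group_by(.data$repclass) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(level = "class", subclass = NA_character_, family = NA_character_)
  erv_all <- tibble(
    level = "class_group", repclass = "ERVAll", subclass = NA_character_,
    family = NA_character_,
    count = sum(cls$count[cls$repclass %in% c("ERV1", "ERV2", "ERV3")])
  )
  total <- tibble(level = "total", repclass = NA_character_,
                  subclass = NA_character_, family = "All",
                  count = nrow(asg))
  unasg <- tibble(level = "unassigned", repclass = NA_character_,
                  subclass = NA_character_, family = "UNASSIGNED",
                  count = n_total - nrow(asg))
  out <- bind_rows(fam, sub, cls, erv_all, total, unasg) |>
    mutate(percent = pct(.data$count)) |>
    select("level", "repclass", "subclass", "family", "count", "percent")
  structure(out, n_total = n_total, zero_denominator = n_total == 0L,
            class = c("composition_table", class(out)))
}

#' Headline composition summary
#'
#' Collapses a composition table onto the headline rows used for
#' chromocenter read sets: the two pericentromeric satellites, other tandem
#' repeats, telomere repeat, LINE, SINE, DNA transposons, the three ERV
#' classes plus the IAP subclass and the ERV and overall totals.
#'
#' @param ct A `composition_table` from [quantify()].
#' @return A tibble with columns `row` and `percent`.
#' @export
composition_summary <- function(ct) {
  fam <- ct[ct$level == "family", ]
  pc <- function(sel) sum(fam$percent[sel])
  cls <- function(cl) pc(fam$repclass == cl)
  tr_special <- fam$subclass %in% c("MaSat", "MiSat", "telomere")
  tibble(
    row = c("MaSat", "MiSat", "OtherTR", "Tel", "LINE", "SINE", "DNA",
            "ERV1", "ERV2All", "IAP", "ERV3", "ERVAll", "All"),
    percent = c(
      pc(fam$subclass == "MaSat"), pc(fam$subclass == "MiSat"),
      pc(fam$repclass == "TR" & !tr_special), pc(fam$subclass == "telomere"),
      cls("LINE"), cls("SINE"), cls("DNA"),
      cls("ERV1"), cls("ERV2"), pc(fam$subclass == "IAP"), cls("ERV3"),
      cls("ERV1") + cls("ERV2") + cls("ERV3"),
      ct$percent[ct$level == "total"]
    )
  )
}
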