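#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: 37-bp paired-end
#' reads at a ~100-bp median insert, drawn from a repeat mixture matching
#' the chromocenter read-set composition (fractions of all reads, pairs
#' counted as two single reads): MaSat 0.662, MiSat 0.044, other TR 0.009,
#' telomere 0.001, LINE 0.109, SINE 0.021, ERV 0.088 (IAP 0.022, other ERV2
#' 0.029, ERV1 0.005, ERV3 0.032), DNA transposons 0.006; the remainder is
#' unannotated background. LINE reads are drawn from a copy pool in which
#' `line_3prime_bias` of the copies expose only the 3'-terminal
#' `line_fragment_len` window of the consensus.
#'
#' @param seed Integer RNG seed.
#' @param n_reads Total reads to emit (two per pair).
#' @param composition Named fractions per family group; must sum to <= 1.
#' @param read_len Read length in bases.
#' @param insert_median Median insert size in bases (lognormal model).
#' @param insert_sdlog Lognormal sdlog of the insert distribution.
#' @param per_base_error Per-base sequencing substitution probability.
#' @param monomer_divergence Percent divergence of repeat copies from their
#'   consensus.
#' @param line_3prime_bias Fraction of LINE copies truncated to the
#'   3'-terminal window.
#' @param line_fragment_len Length of that 3' window in bases.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_reads = 100000L,
                       composition = default_composition(),
                       read_len = 37L, insert_median = 100,
                       insert_sdlog = 0.25, per_base_error = 0.002,
                       monomer_divergence = 5, line_3prime_bias = 0.8,
                       line_fragment_len = 2000L) {
  if (any(composition < 0)) abort("composition fractions must be >= 0")
  if (sum(composition) > 1 + 1e-12) abort("composition sums to more than 1")
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    abort("composition must be a named vector")
  }
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 composition = composition, read_len = as.integer(read_len),
                 insert_median = insert_median, insert_sdlog = insert_sdlog,
                 per_base_error = per_base_error,
                 monomer_divergence = monomer_divergence,
                 line_3prime_bias = line_3prime_bias,
                 line_fragment_len = as.integer(line_fragment_len)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_composition <- function() {
  c(MaSat = 0.662, MiSat = 0.044, `TRPC-21A` = 0.009, telomere = 0.001,
    L1 = 0.109, B1 = 0.021,
    IAP = 0.022, MMERVK = 0.029, RLTR6 = 0.005, MERVL = 0.032,
    DNAT = 0.006)
}

#' Generate a synthetic repeat consensus library
#'
#' Builds mutually dissimilar random consensuses at field-realistic lengths:
#' 234-bp major satellite and 120-bp minor satellite monomers, an 84-bp
#' additional pericentromeric tandem family, the (TTAGGG)20 telomere
#' reference, a 6.4-kb LINE consensus, a 150-bp SINE, four ~6-kb ERV
#' elements split into internal and LTR records (one ERV1, two ERV2 of which
#' one stands for IAP, one ERV3) and an 800-bp DNA transposon. Content is
#' synthetic (41% GC random sequence), deterministic for a given seed.
#'
#' @param seed Integer RNG seed.
#' @return A [repeat_library()].
#' @export
generate_library <- function(seed = 1L) {
  with_seed(seed, {
    rnd <- function(n) random_dna(n)
    rec <- function(name, repclass, subclass, len, tandem = FALSE,
                    te_part = "none") {
      tibble(name = name, repclass = repclass, subclass = subclass,
             is_tandem = tandem,
             monomer_len = if (tandem) len else NA_integer_,
             te_part = te_part, is_expanded = FALSE, seq = rnd(len))
    }
    erv <- function(group, repclass, int_len, ltr_len) {
      bind_rows(
        rec(paste0(group, "-int"), repclass, group, int_len,
            te_part = "internal"),
        rec(paste0(group, "-LTR"), repclass, group, ltr_len,
            te_part = "LTR"))
    }
    records <- bind_rows(
      rec("MaSat", "TR", "MaSat", 234L, tandem = TRUE),
      rec("MiSat", "TR", "MiSat", 120L, tandem = TRUE),
      rec("TRPC-21A", "TR", "TRPC-21A", 84L, tandem = TRUE),
      build_telomere_reference(20L),
      rec("L1", "LINE", "L1", 6400L),
      rec("B1", "SINE", "B1", 150L),
      erv("RLTR6", "ERV1", 5000L, 450L),
      erv("IAP", "ERV2", 5300L, 500L),
      erv("MMERVK", "ERV2", 5200L, 400L),
      erv("MERVL", "ERV3", 4800L, 500L),
      rec("DNAT", "DNA", "DNAT", 800L)
    )
    repeat_library(records)
  })
}

# Source sequence pools per composition group. Tandem groups yield one long
# mutated head-to-tail array; the LINE group a truncation-biased copy pool;
# ERV groups full LTR-internal-LTR elements; `background` random DNA.
build_source_pools <- function(cfg, lib) {
  d <- cfg$monomer_divergence / 100
  pools <- list()
  for (group in names(cfg$composition)) {
    recs <- lib[lib$subclass == group, ]
    if (nrow(recs) == 0L) {
      abort(sprintf("composition group '%s' has no library record", group))
    }
    if (isTRUE(recs$is_tandem[1])) {
      unit <- recs$seq[1]
      n_copies <- max(30L, ceiling(4000 / nchar(unit)))
      pools[[group]] <- paste(
        vapply(seq_len(n_copies), function(i) mutate_dna(unit, d), ""),
        collapse = "")
    } else if (recs$repclass[1] == "LINE") {
      full <- recs$seq[1]
      n_copies <- 25L
      n_trunc <- round(cfg$line_3prime_bias * n_copies)
      win <- substr(full, nchar(full) - cfg$line_fragment_len + 1L,
                    nchar(full))
      pool <- c(rep(win, n_trunc), rep(full, n_copies - n_trunc))
      pools[[group]] <- vapply(pool, mutate_dna, "", rate = d,
                               USE.NAMES = FALSE)
    } else if (any(recs$te_part != "none")) {
      ltr <- recs$seq[recs$te_part == "LTR"][1]
      int <- recs$seq[recs$te_part == "internal"][1]
      element <- paste0(ltr, int, ltr)
      pools[[group]] <- vapply(seq_len(8L), function(i) {
        mutate_dna(element, d)
      }, "")
    } else {
      pools[[group]] <- vapply(seq_len(10L), function(i) {
        mutate_dna(recs$seq[1], d)
      }, "")
    }
  }
  pools$background <- vapply(seq_len(3L), function(i) random_dna(30000L), "")
  pools
}

#' Generate a synthetic chromocenter-like read set
#'
#' Draws read pairs family-by-family from a seeded multinomial at the
#' configured composition, samples insert positions from per-family source
#' pools (mutated tandem arrays, so junction-spanning reads occur; a
#' truncation-biased LINE copy pool; full ERV elements), applies per-base
#' sequencing errors and emits phred+33 qualities. Deterministic for a given
#' config.
#'
#' @param cfg A [sim_config()].
#' @param lib A [repeat_library()] (normally [generate_library()]).
#' @return List with `reads` (tibble `id`, `seq`, `qual`), `truth` (tibble
#'   `read_id`, `pair_id`, `mate`, `family`, `repclass`) and `realized`
#'   (tibble of realized per-group read fractions).
#' @export
generate_reads <- function(cfg, lib) {
  stopifnot(inherits(cfg, "sim_config"))
  if (sum(cfg$composition) > 1 + 1e-12) {
    abort("composition sums to more than 1")
  }
  with_seed(cfg$seed, {
    pools <- build_source_pools(cfg, lib)
    groups <- c(names(cfg$composition), "background")
    probs <- c(cfg$composition, background = 1 - sum(cfg$composition))
    n_pairs <- cfg$n_reads %/% 2L
    counts <- as.integer(rmultinom(1L, n_pairs, probs))
    names(counts) <- groups

    rl <- cfg$read_len
    m1 <- m2 <- fam <- character(0)
    for (g in groups) {
      k <- counts[[g]]
      if (k == 0L) next
      S <- pools[[g]]
      L <- nchar(S)
      idx <- sample.int(length(S), k, replace = TRUE)
      ins <- round(rlnorm(k, log(cfg$insert_median), cfg$insert_sdlog))
      ins <- pmin(pmax(ins, rl), pmin(L[idx], 600L))
      start <- floor(runif(k) * (L[idx] - ins + 1)) + 1L
      frag <- substr(S[idx], start, start + ins - 1L)
      m1 <- c(m1, substr(frag, 1L, rl))
      m2 <- c(m2, revcomp(substr(frag, nchar(frag) - rl + 1L, nchar(frag))))
      fam <- c(fam, rep(g, k))
    }
    # interleave mates: pair i -> reads 2i-1, 2i
    n_out <- 2L * length(m1)
    seqs <- character(n_out)
    seqs[seq(1L, n_out, by = 2L)] <- m1
    seqs[seq(2L, n_out, by = 2L)] <- m2

    # sequencing errors
    if (cfg$per_base_error > 0) {
      nerr <- rbinom(n_out, nchar(seqs), cfg$per_base_error)
      for (i in which(nerr > 0L)) {
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(length(chars), nerr[i])
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, "")
        seqs[i] <- paste(chars, collapse = "")
      }
    }

    # qualities: high-quality MiSeq-like, Q33..Q40 per base
    lens <- nchar(seqs)
    offs <- cumsum(c(0L, lens))
    allq <- sample.int(8L, offs[n_out + 1L], replace = TRUE) + 65L  # Q33..Q40
    bigq <- intToUtf8(allq)
    quals <- substring(bigq, offs[-length(offs)] + 1L, offs[-1L])

    pair_id <- rep(seq_along(m1), each = 2L)
    mate <- rep(c(1L, 2L), length(m1))
    ids <- sprintf("sim_%07d/%d", pair_id, mate)
    reads <- tibble(id = ids, seq = seqs, qual = quals)
    fam2 <- rep(fam, each = 2L)
    truth <- tibble(read_id = ids, pair_id = pair_id, mate = mate,
                    family = fam2,
                    repclass = lib$repclass[match(fam2, lib$subclass)])
    realized <- tibble(family = groups,
                       fraction = 2 * counts / cfg$n_reads)
    list(reads = reads, truth = truth, realized = realized)
  })
}

#' Generate synthetic contigs from blueprints
#'
#' A blueprint is a tibble with one row per feature in contig order:
#' `contig_id`, `kind` (`"array"`, `"te"` or `"spacer"`), `family` (library
#' record name for arrays/te, ignored for spacers), `n` (monomer copies for
#' arrays, length in bases for te fragments and spacers) and optional
#' `strand` (`"+"`/`"-"`, default `"+"`). Array copies are mutated at
#' `divergence` percent; te fragments are windows of the named record.
#'
#' @param blueprints Blueprint tibble.
#' @param lib A [repeat_library()].
#' @param seed Integer RNG seed.
#' @param divergence Percent divergence of planted copies from consensus.
#' @return List with `contigs` (tibble `contig_id`, `seq`) and `features`
#'   (tibble of planted feature coordinates, 1-based inclusive).
#' @export
generate_contigs <- function(blueprints, lib, seed = 1L, divergence = 5) {
  blueprints <- as_tibble(blueprints)
  if (!"strand" %in% names(blueprints)) blueprints$strand <- "+"
  blueprints$strand[is.na(blueprints$strand)] <- "+"
  d <- divergence / 100
  known <- lib$name
  bad <- blueprints$kind %in% c("array", "te") &
    !(blueprints$family %in% known)
  if (any(bad)) {
    abort(paste("blueprint references unknown feature(s):",
                paste(unique(blueprints$family[bad]), collapse = ", ")))
  }
  with_seed(seed, {
    contig_ids <- unique(blueprints$contig_id)
    feats <- list()
    seqs <- character(length(contig_ids))
    for (ci in seq_along(contig_ids)) {
      bp <- blueprints[blueprints$contig_id == contig_ids[ci], ]
      pieces <- character(nrow(bp))
      pos <- 0L
      for (i in seq_len(nrow(bp))) {
        kind <- bp$kind[i]
        if (kind == "spacer") {
          piece <- random_dna(bp$n[i])
        } else if (kind == "array") {
          rec <- lib[lib$name == bp$family[i], ]
          if (!isTRUE(rec$is_tandem)) {
            abort(sprintf("blueprint array family '%s' is not tandem",
                          bp$family[i]))
          }
          piece <- paste(vapply(seq_len(bp$n[i]), function(j) {
            mutate_dna(rec$seq, d)
          }, ""), collapse = "")
          if (bp$strand[i] == "-") piece <- revcomp(piece)
        } else if (kind == "te") {
          rec <- lib[lib$name == bp$family[i], ]
          len <- bp$n[i]
          if (len > nchar(rec$seq)) {
            abort(sprintf("blueprint asks for %d bases of '%s' (%d bp long)",
                          len, rec$name, nchar(rec$seq)))
          }
          start <- sample.int(nchar(rec$seq) - len + 1L, 1L)
          piece <- mutate_dna(substr(rec$seq, start, start + len - 1L), d)
          if (bp$strand[i] == "-") piece <- revcomp(piece)
        } else {
          abort(sprintf("unknown blueprint kind '%s'", kind))
        }
        pieces[i] <- piece
        feats[[length(feats) + 1L]] <- tibble(
          contig_id = contig_ids[ci], kind = kind,
          family = if (kind == "spacer") NA_character_ else bp$family[i],
          start = pos + 1L, end = pos + nchar(piece),
          strand = bp$strand[i], n = bp$n[i])
        pos <- pos + nchar(piece)
      }
      seqs[ci] <- paste(pieces, collapse = "")
    }
    list(contigs = tibble(contig_id = contig_ids, seq = seqs),
         features = list_rbind(feats))
  })
}

#' Intended screen verdicts from a blueprint
#'
#' Applies the co-occurrence positivity rule directly to the blueprint
#' (planted monomer counts and TE fragment lengths), independent of any
#' alignment, giving the ground truth for [screen_batch()].
#'
#' @param blueprints Blueprint tibble (see [generate_contigs()]).
#' @param lib A [repeat_library()].
#' @param criteria A [screen_criteria()].
#' @return Tibble `contig_id`, `tr_family`, `positive`.
#' @export
blueprint_verdicts <- function(blueprints, lib, criteria) {
  blueprints <- as_tibble(blueprints)
  purrr::map(unique(blueprints$contig_id), function(id) {
    bp <- blueprints[blueprints$contig_id == id, ]
    part <- lib$te_part[match(bp$family, lib$name)]
    monomers <- sum(bp$n[bp$kind == "array" &
                           bp$family == criteria$tr_family])
    qual <- bp$kind == "te" & !is.na(part) & part != "none" &
      bp$n > criteria$min_te_fragment_len
    if (criteria$ltr_only) qual <- qual & part == "LTR"
    tibble(contig_id = id, tr_family = criteria$tr_family,
           positive = monomers >= criteria$min_monomers && any(qual))
  }) |> list_rbind()
}
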