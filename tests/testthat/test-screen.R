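test_that("an exact LTR copy is annotated with its full length", {
  lib <- fixture_lib()
  ltr <- lib$seq[lib$name == "RLTR6-LTR"]  # 450 bp
  contig <- paste0(random_seq(200), ltr, random_seq(200))
  set.seed(61)
  fr <- annotate_te(contig, lib)
  fr <- fr[fr$te_name == "RLTR6-LTR", ]
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$length, 450L)
  expect_identical(fr$te_part, "LTR")
  expect_lt(fr$evalue, 1e-10)
})

test_that("weak spurious matches are discarded by the e-value/score rule", {
  lib <- fixture_lib()
  set.seed(62)
  # 60-base decoy at ~75% identity to an IAP-LTR window: the alignment
  # passes the reporting floor but fails both retention thresholds
  window <- substr(lib$seq[lib$name == "IAP-LTR"], 101, 160)
  decoy <- mutate_k(window, 15)
  contig <- paste0(random_seq(1000), decoy, random_seq(1000))
  fr <- annotate_te(contig, lib)
  expect_identical(nrow(fr[fr$te_name == "IAP-LTR", ]), 0L)
  # oracle on the thresholds: the hit exists, scores in [40, 100) and its
  # expectation is far above 1e-10
  a <- align_local(lib$seq[lib$name == "IAP-LTR"], contig)
  expect_gte(a$score, 40L)
  expect_lt(a$score, 100L)
  ev <- chromoscan:::karlin_evalue(a$score, 500, nchar(contig),
                                   scoring_scheme())
  expect_gt(ev, 1e-10)
  # score_only mode applies the same floor without the e-value escape
  fr2 <- annotate_te(contig, lib, score_only = TRUE, min_keep_score = 100)
  expect_identical(nrow(fr2[fr2$te_name == "IAP-LTR", ]), 0L)
})

test_that("LTR-internal-LTR layouts annotate in order with correct parts", {
  lib <- fixture_lib()
  ltr <- lib$seq[lib$name == "IAP-LTR"]
  int <- substr(lib$seq[lib$name == "IAP-int"], 1, 2000)
  contig <- paste0(random_seq(100), ltr, int, ltr, random_seq(100))
  fr <- annotate_te(contig, lib)
  fr <- fr[fr$te_name %in% c("IAP-LTR", "IAP-int"), ]
  expect_identical(nrow(fr), 3L)
  expect_identical(fr$te_part, c("LTR", "internal", "LTR"))
  expect_true(!is.unsorted(fr$start))
})

test_that("screen verdicts implement the positivity rule and its boundaries", {
  lib <- fixture_lib()
  bps <- dplyr::bind_rows(
    tibble::tibble(contig_id = "a", kind = c("array", "spacer", "te"),
                   family = c("MaSat", NA, "IAP-LTR"), n = c(2, 100, 500)),
    tibble::tibble(contig_id = "b", kind = c("array", "te"),
                   family = c("TRPC-21A", "IAP-LTR"), n = c(2, 500)),
    tibble::tibble(contig_id = "c", kind = c("array", "spacer", "te"),
                   family = c("MaSat", NA, "MMERVK-LTR"), n = c(5, 100, 400)))
  g <- generate_contigs(bps, lib, seed = 63, divergence = 0)
  seqs <- g$contigs
  # 2 MaSat monomers + 500-bp LTR -> positive
  ra <- screen_contig(seqs$seq[seqs$contig_id == "a"],
                      screen_criteria("MaSat"), lib, contig_id = "a")
  expect_true(ra$positive)
  # 2 TRPC-21A monomers: below the 3-monomer requirement
  rb <- screen_contig(seqs$seq[seqs$contig_id == "b"],
                      screen_criteria("TRPC-21A", min_monomers = 3), lib,
                      contig_id = "b")
  expect_false(rb$positive)
  expect_identical(rb$n_monomers, 2L)
  # TE fragment of exactly 400 bases: strict > 400 makes it negative
  rc_ <- screen_contig(seqs$seq[seqs$contig_id == "c"],
                       screen_criteria("MaSat"), lib, contig_id = "c")
  expect_false(rc_$positive)
  expect_identical(rc_$best_te_len, 400L)
  expect_identical(rc_$n_monomers, 5L)
  expect_error(screen_contig(seqs$seq[1], screen_criteria("NOSUCH"), lib),
               "NOSUCH")
})

test_that("positivity is monotone in TE fragment evidence", {
  lib <- fixture_lib()
  bp <- tibble::tibble(contig_id = "m", kind = "array", family = "MaSat",
                       n = 3)
  g <- generate_contigs(bp, lib, seed = 64, divergence = 0)
  base <- g$contigs$seq[1]
  cr <- screen_criteria("MaSat")
  expect_false(screen_contig(base, cr, lib)$positive)
  # appending a qualifying fragment flips it positive
  withltr <- paste0(base, lib$seq[lib$name == "MERVL-LTR"])
  expect_true(screen_contig(withltr, cr, lib)$positive)
  # only sub-threshold fragments -> stays negative
  short <- paste0(base, substr(lib$seq[lib$name == "MERVL-LTR"], 1, 380))
  expect_false(screen_contig(short, cr, lib)$positive)
})

test_that("structure maps partition the contig without gaps or overlaps", {
  lib <- fixture_lib()
  bp <- tibble::tibble(contig_id = "s", kind = c("array", "spacer", "te"),
                       family = c("MaSat", NA, "IAP-LTR"), n = c(3, 200, 500))
  g <- generate_contigs(bp, lib, seed = 65, divergence = 2)
  r <- screen_contig(g$contigs$seq[1], screen_criteria("MaSat"), lib,
                     contig_id = "s")
  smap <- r$structure_map[[1]]
  expect_identical(smap$start[1], 1L)
  expect_identical(smap$end[nrow(smap)], nchar(g$contigs$seq[1]))
  expect_identical(smap$start[-1], smap$end[-nrow(smap)] + 1L)
  expect_setequal(unique(smap$type),
                  c("TR_array", "TE_LTR", "unannotated"))
})

test_that("batch screening is deterministic and validates ids", {
  lib <- fixture_lib()
  bp <- tibble::tibble(contig_id = c("x", "y"), kind = "spacer",
                       family = NA_character_, n = 400)
  g <- generate_contigs(bp, lib, seed = 66)
  out1 <- screen_batch(g$contigs, screen_criteria("MaSat"), lib)
  out2 <- screen_batch(g$contigs, screen_criteria("MaSat"), lib)
  expect_identical(out1$counts, out2$counts)
  expect_identical(out1$results$positive, out2$results$positive)
  expect_identical(sum(out1$results$positive), 0L)
  dup <- dplyr::bind_rows(g$contigs, g$contigs[1, ])
  expect_error(screen_batch(dup, screen_criteria("MaSat"), lib), "duplicate")
  # empty contig set: zero counts
  out0 <- screen_batch(g$contigs[0, ], screen_criteria("MaSat"), lib)
  expect_identical(nrow(out0$results), 0L)
})
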