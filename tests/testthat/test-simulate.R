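test_that("library generation is deterministic and uses the stated lengths", {
  lib1 <- generate_library(1)
  lib2 <- generate_library(1)
  expect_identical(lib1$seq, lib2$seq)
  expect_false(identical(generate_library(2)$seq, lib1$seq))
  expect_identical(nchar(lib1$seq[lib1$name == "MaSat"]), 234L)
  expect_identical(nchar(lib1$seq[lib1$name == "MiSat"]), 120L)
  expect_identical(lib1$seq[lib1$name == "TEL"], strrep("TTAGGG", 20))
  # ERV elements are ~6 kb (LTR + internal + LTR)
  for (g in c("RLTR6", "IAP", "MMERVK", "MERVL")) {
    tot <- sum(nchar(lib1$seq[lib1$subclass == g])) +
      nchar(lib1$seq[lib1$subclass == g & lib1$te_part == "LTR"])
    expect_gt(tot, 5500)
    expect_lt(tot, 6500)
  }
})

test_that("synthetic consensuses are mutually dissimilar", {
  lib <- fixture_lib()
  seqs <- lib$seq
  n <- length(seqs)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      a <- align_local(seqs[i], seqs[j],
                       scoring_scheme(min_score = 1L, min_aln_len = 1L))
      shared <- if (nrow(a)) a$matches else 0
      ident <- 100 * shared / min(nchar(seqs[i]), nchar(seqs[j]))
      expect_lt(ident, 55)
    }
  }
})

test_that("read generation is deterministic down to FASTQ bytes", {
  lib <- fixture_lib()
  cfg <- sim_config(seed = 71, n_reads = 600)
  s1 <- generate_reads(cfg, lib)
  s2 <- generate_reads(cfg, lib)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(s1$reads, f1)
  write_fastq(s2$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(generate_reads(sim_config(seed = 72, n_reads = 600),
                                        lib)$reads$seq, s1$reads$seq))
})

test_that("noise-free reads are exact substrings of their source references", {
  lib <- fixture_lib()
  cfg <- sim_config(seed = 73, n_reads = 400, per_base_error = 0,
                    monomer_divergence = 0)
  sim <- generate_reads(cfg, lib)
  for (i in seq_len(nrow(sim$reads))) {
    fam <- sim$truth$family[i]
    if (fam == "background") next
    recs <- lib[lib$subclass == fam, ]
    ref <- if (isTRUE(recs$is_tandem[1])) {
      strrep(recs$seq[1], 40)
    } else if (any(recs$te_part != "none")) {
      ltr <- recs$seq[recs$te_part == "LTR"][1]
      paste0(ltr, recs$seq[recs$te_part == "internal"][1], ltr)
    } else {
      recs$seq[1]
    }
    s <- sim$reads$seq[i]
    expect_true(grepl(s, ref, fixed = TRUE) ||
                  grepl(rc(s), ref, fixed = TRUE),
                label = sprintf("read %d from %s is a source substring", i, fam))
  }
})

test_that("realized composition tracks the configured fractions", {
  lib <- fixture_lib()
  sim <- generate_reads(sim_config(seed = 74, n_reads = 20000), lib)
  target <- c(default_composition(),
              background = 1 - sum(default_composition()))
  got <- setNames(sim$realized$fraction, sim$realized$family)
  expect_true(all(abs(got[names(target)] - target) < 0.01))
  # truth covers every read exactly once
  expect_identical(nrow(sim$truth), nrow(sim$reads))
  expect_identical(anyDuplicated(sim$truth$read_id), 0L)
})

test_that("realized composition converges with read depth", {
  lib <- fixture_lib()
  dev <- function(n) {
    sim <- generate_reads(sim_config(seed = 75, n_reads = n), lib)
    target <- c(default_composition(),
                background = 1 - sum(default_composition()))
    got <- setNames(sim$realized$fraction, sim$realized$family)
    sum(abs(got[names(target)] - target))
  }
  expect_lt(dev(100000), dev(10000))
})

test_that("contig blueprints are honoured and validated", {
  lib <- fixture_lib()
  bp <- tibble::tibble(contig_id = "c", kind = c("array", "spacer", "te"),
                       family = c("MaSat", NA, "IAP-LTR"), n = c(2, 100, 500))
  g <- generate_contigs(bp, lib, seed = 76, divergence = 0)
  expect_identical(nchar(g$contigs$seq), 2L * 234L + 100L + 500L)
  f <- g$features
  expect_identical(f$end[nrow(f)], nchar(g$contigs$seq))
  # with zero divergence the planted array is literally monomer copies
  arr <- substr(g$contigs$seq, f$start[1], f$end[1])
  expect_identical(arr, strrep(lib$seq[lib$name == "MaSat"], 2))
  expect_error(generate_contigs(
    tibble::tibble(contig_id = "c", kind = "te", family = "NOSUCH", n = 10),
    lib), "unknown feature")
  expect_error(generate_contigs(
    tibble::tibble(contig_id = "c", kind = "te", family = "IAP-LTR", n = 900),
    lib), "900")
})

test_that("blueprint verdicts apply the positivity rule directly", {
  lib <- fixture_lib()
  bps <- dplyr::bind_rows(
    tibble::tibble(contig_id = "p", kind = c("array", "te"),
                   family = c("MaSat", "IAP-LTR"), n = c(2, 500)),
    tibble::tibble(contig_id = "n", kind = c("array", "te"),
                   family = c("TRPC-21A", "IAP-LTR"), n = c(2, 500)),
    tibble::tibble(contig_id = "s", kind = "spacer",
                   family = NA_character_, n = 5000))
  v <- blueprint_verdicts(bps, lib, screen_criteria("MaSat"))
  expect_identical(v$positive, c(TRUE, FALSE, FALSE))
  v2 <- blueprint_verdicts(bps, lib,
                           screen_criteria("TRPC-21A", min_monomers = 3))
  expect_identical(v2$positive, c(FALSE, FALSE, FALSE))
})

test_that("composition fractions summing above one are rejected", {
  expect_error(sim_config(composition = c(MaSat = 0.7, MiSat = 0.4)),
               "more than 1")
})
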