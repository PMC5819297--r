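test_that("exact monomer copies yield abutting full-identity hits", {
  lib <- fixture_lib()
  ma <- lib[lib$name == "MaSat", ]
  contig <- strrep(ma$seq, 5)
  h <- find_monomer_hits(contig, ma)
  expect_identical(nrow(h), 5L)
  expect_true(all(h$identity == 100))
  expect_identical(h$start, as.integer(seq(1, by = 234, length.out = 5)))
  expect_identical(h$end, h$start + 233L)
  expect_true(all(h$strand == "+"))
})

test_that("a diverged single copy is still found above the identity floor", {
  lib <- fixture_lib()
  ma <- lib[lib$name == "MaSat", ]
  set.seed(51)
  copy <- mutate_k(ma$seq, 40)  # ~83% identity
  contig <- paste0(random_seq(300), copy, random_seq(300))
  h <- find_monomer_hits(contig, ma)
  expect_identical(nrow(h), 1L)
  expect_gte(h$identity, 75)
  expect_lt(h$identity, 95)
  # independent check on the claimed identity for this seeded mutant
  a <- align_local(ma$seq, contig)
  expect_equal(h$identity, a$identity)
})

test_that("random contigs contain no monomer hits", {
  lib <- fixture_lib()
  set.seed(52)
  contig <- random_seq(3000)
  h <- find_monomer_hits(contig, lib[lib$name == "MaSat", ])
  expect_identical(nrow(h), 0L)
  # oracle: best local score against the monomer is below the floor
  expect_lt(sw_oracle_best(lib$seq[lib$name == "MaSat"], contig), 40)
})

test_that("minus-strand arrays are found with the correct strand label", {
  lib <- fixture_lib()
  mi <- lib[lib$name == "MiSat", ]
  contig <- paste0(random_seq(200), rc(strrep(mi$seq, 4)), random_seq(200))
  h <- find_monomer_hits(contig, mi)
  expect_identical(nrow(h), 4L)
  expect_true(all(h$strand == "-"))
  arr <- chain_arrays(h, monomer_len = 120L)
  expect_identical(nrow(arr), 1L)
  expect_identical(arr$n_monomers, 4L)
})

test_that("the large-TR rule is applied at the 3-kb span boundary", {
  lib <- fixture_lib()
  ma <- lib[lib$name == "MaSat", ]
  # 13 abutting copies: span 3042 > 3000
  h13 <- find_monomer_hits(strrep(ma$seq, 13), ma)
  a13 <- chain_arrays(h13, monomer_len = 234L)
  expect_identical(nrow(a13), 1L)
  expect_identical(a13$n_monomers, 13L)
  expect_identical(a13$span, 3042L)
  expect_true(a13$meets_large_TR)
  # 12 copies: span 2808 < 3000
  a12 <- chain_arrays(find_monomer_hits(strrep(ma$seq, 12), ma),
                      monomer_len = 234L)
  expect_identical(a12$span, 2808L)
  expect_false(a12$meets_large_TR)
  # a long array of long monomers fails the monomer-length clause
  a_long <- chain_arrays(
    tibble::tibble(start = 1L, end = 4000L, strand = "+", score = 8000L,
                   identity = 100, hit_len = 4000L),
    monomer_len = 4000L)
  expect_false(a_long$meets_large_TR)
})

test_that("an insert larger than the gap tolerance splits the array", {
  lib <- fixture_lib()
  ma <- lib[lib$name == "MaSat", ]
  contig <- paste0(strrep(ma$seq, 5), random_seq(500), strrep(ma$seq, 5))
  h <- find_monomer_hits(contig, ma)
  arr <- chain_arrays(h, monomer_len = 234L)
  expect_identical(nrow(arr), 2L)
  expect_identical(arr$n_monomers, c(5L, 5L))
  # conservation: chained hits are exactly the input hits
  expect_identical(sum(arr$n_hits), nrow(h))
  # arrays of the same family and strand never overlap
  expect_true(all(arr$start[-1] > arr$end[-nrow(arr)]))
})

test_that("planted arrays are recovered with full interval recall and precision", {
  lib <- fixture_lib()
  bps <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(contig_id = sprintf("t%02d", i),
                   kind = c("spacer", "array", "spacer"),
                   family = c(NA, if (i %% 2) "MaSat" else "MiSat", NA),
                   n = c(100 * i, 4 + i, 200))
  }))
  g <- generate_contigs(bps, lib, seed = 53, divergence = 12)
  truth <- g$features[g$features$kind == "array", ]
  found <- dplyr::bind_rows(
    find_tandem_arrays(g$contigs, lib, "MaSat"),
    find_tandem_arrays(g$contigs, lib, "MiSat"))
  # every planted array matched by a call with >= 50% reciprocal overlap
  recip <- function(a1, a2, b1, b2) {
    ov <- max(0, min(a2, b2) - max(a1, b1) + 1)
    ov >= 0.5 * (a2 - a1 + 1) && ov >= 0.5 * (b2 - b1 + 1)
  }
  hit <- logical(nrow(truth))
  used <- logical(nrow(found))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(found))) {
      if (truth$contig_id[i] == found$contig_id[j] &&
          truth$family[i] == found$family[j] &&
          recip(truth$start[i], truth$end[i], found$start[j], found$end[j])) {
        hit[i] <- TRUE
        used[j] <- TRUE
      }
    }
  }
  expect_true(all(hit))   # recall 1.0
  expect_true(all(used))  # precision 1.0
  # complete-copy counts match the planted copy numbers
  key_t <- paste(truth$contig_id, truth$family)
  key_f <- paste(found$contig_id, found$family)
  expect_identical(found$n_monomers[match(key_t, key_f)], as.integer(truth$n))
})
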