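test_that("a single read increments exactly its aligned span", {
  lib <- fixture_lib()
  l1 <- lib[lib$name == "L1", ]
  reads <- reads_from_seqs(substr(l1$seq, 101, 137))
  p <- profile_coverage(reads, l1)
  expect_equal(sum(p$coverage), 37)
  expect_true(all(p$coverage[101:137] == 1))
  expect_true(all(p$coverage[-(101:137)] == 0))
})

test_that("empty read stream gives an all-zero profile", {
  lib <- fixture_lib()
  p <- profile_coverage(reads_from_seqs(character(0)), lib[lib$name == "L1", ])
  expect_true(all(p$coverage == 0))
  expect_identical(nrow(p), 6400L)
})

test_that("profile mass equals total aligned bases", {
  lib <- fixture_lib()
  cfg <- sim_config(seed = 41, n_reads = 1000, composition = c(L1 = 1))
  sim <- generate_reads(cfg, lib)
  l1 <- lib[lib$name == "L1", ]
  p <- profile_coverage(sim$reads, l1)
  # cross-check with the classifier's reported spans on the same reads
  a <- classify_reads(sim$reads, repeat_library(l1))
  spans <- a$ref_end - a$ref_start + 1L
  expect_equal(sum(p$coverage), sum(spans, na.rm = TRUE))
})

test_that("uniformly sampled full-length reads give a near-flat profile", {
  lib <- fixture_lib()
  cfg <- sim_config(seed = 42, n_reads = 20000, composition = c(L1 = 1),
                    line_3prime_bias = 0, per_base_error = 0,
                    monomer_divergence = 0)
  sim <- generate_reads(cfg, lib)
  p <- profile_coverage(sim$reads, lib[lib$name == "L1", ])
  inner <- p$coverage[300:6100]  # away from unavoidable edge falloff
  expect_lt(max(inner) / median(inner), 1.5)
})

test_that("tandem consensus coverage folds onto the monomer", {
  lib <- fixture_lib()
  ma <- lib[lib$name == "MaSat", ]
  jq <- paste0(substr(ma$seq, 217, 234), substr(ma$seq, 1, 19))
  p <- profile_coverage(reads_from_seqs(jq), ma)
  expect_identical(nrow(p), 234L)
  expect_equal(sum(p$coverage), 37)
  expect_true(all(p$coverage[c(1:19, 217:234)] == 1))
})

test_that("normalization is reads-per-million and refuses double application", {
  lib <- fixture_lib()
  cfg <- sim_config(seed = 43, n_reads = 2000, composition = c(L1 = 1))
  sim <- generate_reads(cfg, lib)
  p <- profile_coverage(sim$reads, lib[lib$name == "L1", ])
  # per == dataset size leaves values unchanged
  same <- normalize_profile(p, per = attr(p, "n_reads_total"))
  expect_equal(same$coverage, p$coverage)
  pn <- normalize_profile(p)
  expect_equal(pn$coverage, p$coverage * 1e6 / 2000)
  expect_error(normalize_profile(pn), "already normalized")
  p0 <- profile_coverage(reads_from_seqs(character(0)), lib[lib$name == "L1", ])
  expect_error(normalize_profile(p0), "zero reads")
})

test_that("normalized profiles from different depths agree within sampling error", {
  lib <- fixture_lib()
  p1 <- profile_coverage(
    generate_reads(sim_config(seed = 44, n_reads = 4000,
                              composition = c(L1 = 1)), lib)$reads,
    lib[lib$name == "L1", ]) |> normalize_profile()
  p2 <- profile_coverage(
    generate_reads(sim_config(seed = 45, n_reads = 20000,
                              composition = c(L1 = 1)), lib)$reads,
    lib[lib$name == "L1", ]) |> normalize_profile()
  nz <- p1$coverage > 0 & p2$coverage > 0
  ratio <- p1$coverage[nz] / p2$coverage[nz]
  expect_gt(median(ratio), 0.8)
  expect_lt(median(ratio), 1.25)
})

test_that("segment calling handles flat, planted and paired windows", {
  mkprof <- function(values) {
    chromoscan:::new_coverage_profile(values, "synthetic", 1000L, 1000L)
  }
  # flat profile: nothing above threshold
  expect_identical(nrow(detect_enriched_segments(mkprof(rep(10, 5000)))), 0L)
  # all-zero profile: zero median handled by returning no calls
  expect_identical(nrow(detect_enriched_segments(mkprof(rep(0, 5000)))), 0L)

  # one planted 800-bp window at 10x background
  v <- rep(10, 5000)
  v[2001:2800] <- 100
  seg <- detect_enriched_segments(mkprof(v))
  expect_identical(nrow(seg), 1L)
  expect_lt(abs(seg$start - 2001), 60)
  expect_lt(abs(seg$end - 2800), 60)
  expect_gt(seg$mean_fold, 3)

  # two windows separated by more than the smoothing window: two calls in order
  v2 <- rep(10, 5000)
  v2[1001:1400] <- 100
  v2[3001:3400] <- 100
  seg2 <- detect_enriched_segments(mkprof(v2))
  expect_identical(nrow(seg2), 2L)
  expect_true(seg2$start[1] < seg2$start[2])

  # nearby runs (gap < smooth_window) merge into one call
  v3 <- rep(10, 5000)
  v3[1001:1400] <- 100
  v3[1450:1850] <- 100
  expect_identical(nrow(detect_enriched_segments(mkprof(v3))), 1L)
})

test_that("segment calls are scale-free and mirror-symmetric", {
  set.seed(46)
  v <- rep(10, 5000) + runif(5000)
  v[3500:4700] <- v[3500:4700] * 8
  mkprof <- function(values) {
    chromoscan:::new_coverage_profile(values, "synthetic", 1000L, 1000L)
  }
  s1 <- detect_enriched_segments(mkprof(v))
  s2 <- detect_enriched_segments(mkprof(v * 1000))
  expect_equal(s1, s2)
  # reversed profile gives mirrored coordinates
  s3 <- detect_enriched_segments(mkprof(rev(v)))
  expect_identical(nrow(s3), nrow(s1))
  expect_equal(s3$start, rev(5000 - s1$end + 1))
  expect_equal(s3$end, rev(5000 - s1$start + 1))
})

test_that("profile shorter than the smoothing window is rejected", {
  p <- chromoscan:::new_coverage_profile(rep(1, 50), "short", 10L, 10L)
  expect_error(detect_enriched_segments(p), "smooth_window")
})
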