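# Shared fixtures built in code. The library is deterministic for seed 1 and
# cached per test run.
fixture_lib <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- generate_library(1)
    lib
  }
})

# read tibble from bare sequences, constant high quality
reads_from_seqs <- function(seqs, q = 40L) {
  tibble::tibble(
    id = sprintf("r%04d", seq_along(seqs)),
    seq = seqs,
    qual = vapply(nchar(seqs), function(L) strrep(intToUtf8(q + 33L), L), "")
  )
}

# one read with explicit per-base qualities
read_with_quals <- function(seq, quals, id = "r1") {
  stopifnot(nchar(seq) == length(quals))
  tibble::tibble(id = id, seq = seq, qual = intToUtf8(quals + 33L))
}

# The 50-contig blueprint set used for the screen correctness checks.
# Deterministic construction; verdict margins are explicit:
#  - qualifying TE fragments are planted at 500 bp (well above the 400-bp
#    floor), non-qualifying ones at 350 bp or absent;
#  - the exact-400 boundary contigs plant the full-length 400-bp LTR record
#    without divergence, so the measured fragment length is exactly 400;
#  - TRPC-21A monomer-count boundary contigs plant 2 vs 3 copies.
screen_blueprints <- function() {
  bp <- list()
  add <- function(id, kind, family, n) {
    bp[[length(bp) + 1L]] <<- tibble::tibble(
      contig_id = id, kind = kind, family = family, n = n)
  }
  k <- 0
  for (i in 1:12) {  # MaSat + long LTR -> MaSat-positive
    add(sprintf("pos_masat_%02d", i), c("array", "spacer", "te"),
        c("MaSat", NA, "IAP-LTR"), c((i - 1) %% 5 + 1, 150, 500))
  }
  for (i in 1:8) {   # MaSat but no TE -> negative
    add(sprintf("neg_notef_%02d", i), c("array", "spacer"),
        c("MaSat", NA), c((i - 1) %% 5 + 1, 400))
  }
  for (i in 1:6) {   # TE but no TR -> negative
    add(sprintf("neg_notr_%02d", i), c("spacer", "te"),
        c(NA, "IAP-int"), c(300, 800))
  }
  for (i in 1:6) {   # 3 TRPC monomers + LTR -> TRPC-positive
    add(sprintf("pos_trpc3_%02d", i), c("array", "te"),
        c("TRPC-21A", "MERVL-LTR"), c(3, 500))
  }
  for (i in 1:6) {   # 2 TRPC monomers + LTR -> TRPC-negative (needs 3)
    add(sprintf("neg_trpc2_%02d", i), c("array", "te"),
        c("TRPC-21A", "MERVL-LTR"), c(2, 500))
  }
  for (i in 1:4) {   # short TE fragment (350 < 400) -> negative
    add(sprintf("neg_short_%02d", i), c("array", "te"),
        c("MaSat", "RLTR6-LTR"), c(1, 350))
  }
  for (i in 1:4) {   # spacer only -> negative
    add(sprintf("neg_empty_%02d", i), "spacer", NA_character_, 600)
  }
  main <- dplyr::bind_rows(bp)
  # boundary: 5 MaSat monomers + TE fragment of exactly 400 bases
  boundary <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(contig_id = sprintf("neg_te400_%02d", i),
                   kind = c("array", "spacer", "te"),
                   family = c("MaSat", NA, "MMERVK-LTR"),
                   n = c(5, 100, 400))
  }))
  list(main = main, boundary = boundary)
}

# realize the blueprint set: main at 5% divergence, boundary at 0%
screen_contig_set <- function(lib, seed = 20L) {
  bps <- screen_blueprints()
  g1 <- generate_contigs(bps$main, lib, seed = seed, divergence = 5)
  g2 <- generate_contigs(bps$boundary, lib, seed = seed + 1L, divergence = 0)
  list(contigs = dplyr::bind_rows(g1$contigs, g2$contigs),
       blueprints = dplyr::bind_rows(bps$main, bps$boundary))
}
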