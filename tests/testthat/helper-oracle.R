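# Independent brute-force affine-gap local alignment oracle (score only).
# Full (m+1) x (n+1) matrix recurrences, no seeding, no banding -- kept
# deliberately naive and separate from the package's aligner.
sw_oracle_score <- function(a, b, match = 2, mismatch = -3,
                            gap_open = -5, gap_extend = -2) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(A)
  n <- length(B)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-1e9, m + 1, n + 1)
  F <- matrix(-1e9, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                     F[i - 1, j] + gap_extend)
      s <- if (A[i - 1] == B[j - 1] &&
                 A[i - 1] %in% c("A", "C", "G", "T")) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# both-strand oracle score, mirroring what align_local reports
sw_oracle_best <- function(q, r, ...) {
  max(sw_oracle_score(q, r, ...), sw_oracle_score(rc(q), r, ...))
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# substitute exactly k positions of a DNA string (to a different base)
mutate_k <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}
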