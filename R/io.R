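#' Read a FASTQ file into a read tibble
#'
#' Reads are represented throughout the package as a tibble with one row per
#' read and columns `id`, `seq` (DNA string) and `qual` (phred+33 quality
#' string of the same length).
#'
#' @param path Path to a FASTQ file (phred+33).
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) abort(sprintf("malformed FASTQ '%s': %s", path,
                                        conditionMessage(e)))
    ),
    warning = function(w) {
      # the reader parks qualities in metadata columns before pairing them
      # with the sequences; dropping that scratch column is expected
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(
    id = names(x) %||% as.character(seq_along(x)),
    seq = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}

#' Write a read tibble to FASTQ
#'
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual)
  )
  names(x) <- reads$id
  withCallingHandlers(
    Biostrings::writeQualityScaledXStringSet(x, path),
    warning = function(w) {
      # qualities live in metadata columns; dropping them from the sequence
      # track is expected when the writer emits them as the quality lines
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  invisible(path)
}

#' Read a FASTA file into a sequence tibble
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(name = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `name` (or `contig_id`) and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  nm <- if ("name" %in% names(seqs)) seqs$name else seqs$contig_id
  x <- Biostrings::DNAStringSet(seqs$seq)
  names(x) <- nm
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Plain TSV writer used for all tabular reports (deterministic bytes).
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  list_cols <- vapply(df, is.list, logical(1))
  df <- df[, !list_cols, drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a coverage profile as bedGraph
#'
#' The consensus name is used as the "chromosome"; intervals are emitted
#' 0-based half-open with runs of equal coverage merged, per the format.
#'
#' @param p A `coverage_profile` (see [profile_coverage()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(p, path) {
  r <- rle(p$coverage)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  df <- data.frame(chrom = attr(p, "consensus_name"),
                   start = starts, end = ends, value = r$values)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export tandem arrays or structure maps as GFF3
#'
#' Coordinates are written 1-based inclusive per the GFF convention.
#'
#' @param feats Tibble with columns `contig_id`, `start`, `end`, `strand`,
#'   a feature `type` column (or `family`), and optionally `score`.
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(feats, path, source = "chromoscan") {
  type <- if ("type" %in% names(feats)) feats$type else "tandem_array"
  score <- if ("score" %in% names(feats)) feats$score else "."
  attrs <- if ("family" %in% names(feats)) {
    paste0("Name=", feats$family)
  } else if ("feature" %in% names(feats)) {
    paste0("Name=", feats$feature)
  } else "."
  lines <- c("##gff-version 3",
             if (nrow(feats)) {
               paste(feats$contig_id, source, type, feats$start, feats$end,
                     score, feats$strand %||% "+", ".", attrs, sep = "\t")
             })
  writeLines(lines, path)
  invisible(path)
}
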