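#' Build a repeat consensus library
#'
#' A repeat library is a tibble with one row per consensus record and columns
#' `name`, `repclass`, `subclass`, `is_tandem`, `monomer_len`, `te_part`,
#' `is_expanded`, `seq`. `repclass` must be one of `TR`, `LINE`, `SINE`,
#' `ERV1`, `ERV2`, `ERV3`, `DNA`, `OTHER`; `te_part` one of `internal`,
#' `LTR`, `none`. For tandem records (`is_tandem`) the stored sequence is one
#' monomer and `monomer_len` must equal its length, except for records marked
#' `is_expanded`, whose sequence is a pre-expanded run of monomers (the
#' telomere reference is the canonical case).
#'
#' @param records Data frame with at least `name`, `repclass`, `subclass`,
#'   `is_tandem`, `monomer_len`, `te_part`, `seq` (and optionally
#'   `is_expanded`).
#' @param priority Character vector of repclass values used for classifier
#'   tie-breaking; must contain every class present in `records` exactly once.
#' @return A validated `repeat_library` tibble.
#' @export
repeat_library <- function(records, priority = REPEAT_CLASSES) {
  req <- c("name", "repclass", "subclass", "is_tandem", "monomer_len",
           "te_part", "seq")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    abort(paste("library metadata is missing column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  rec <- as_tibble(records)
  if (!"is_expanded" %in% names(rec)) rec$is_expanded <- FALSE
  rec <- rec[, c(req[1:6], "is_expanded", "seq")]
  rec$seq <- clean_dna(rec$seq, "library sequence")
  rec$is_tandem <- as.logical(rec$is_tandem)
  rec$monomer_len <- as.integer(rec$monomer_len)

  if (anyDuplicated(rec$name)) {
    abort(paste("duplicate record name(s):",
                paste(unique(rec$name[duplicated(rec$name)]), collapse = ", ")))
  }
  bad_class <- setdiff(unique(rec$repclass), REPEAT_CLASSES)
  if (length(bad_class)) {
    abort(paste("invalid repclass:", paste(bad_class, collapse = ", ")))
  }
  bad_part <- setdiff(unique(rec$te_part), TE_PARTS)
  if (length(bad_part)) {
    abort(paste("invalid te_part:", paste(bad_part, collapse = ", ")))
  }
  if (any(!nzchar(rec$seq))) abort("empty sequence in library")
  tand <- rec$is_tandem & !rec$is_expanded
  mism <- tand & (is.na(rec$monomer_len) | rec$monomer_len != nchar(rec$seq))
  if (any(mism)) {
    abort(sprintf(
      "monomer_len disagrees with sequence length for tandem record(s): %s",
      paste(rec$name[mism], collapse = ", ")))
  }
  if (any(rec$is_tandem & (is.na(rec$monomer_len) | rec$monomer_len < 1))) {
    abort("tandem records require a positive monomer_len")
  }
  if (anyDuplicated(priority) ||
      length(setdiff(unique(rec$repclass), priority))) {
    abort("`priority` must list each repclass present in the library exactly once")
  }
  structure(rec, priority = priority,
            class = c("repeat_library", class(rec)))
}

#' @export
print.repeat_library <- function(x, ...) {
  cat(sprintf("<repeat_library> %d records (%s)\n", nrow(x),
              paste(unique(x$repclass), collapse = ", ")))
  NextMethod()
}

priority_of <- function(lib) attr(lib, "priority") %||% REPEAT_CLASSES

#' Load a repeat library from FASTA plus a TSV metadata sidecar
#'
#' The sidecar is a 6-column tab-separated table (`name`, `repclass`,
#' `subclass`, `is_tandem`, `monomer_len`, `te_part`, plus an optional
#' `is_expanded` column). Every FASTA record must have a metadata row and
#' vice versa; sequences are uppercased and U is converted to T.
#'
#' @param fasta_path Path to the consensus FASTA.
#' @param metadata_path Path to the TSV sidecar.
#' @inheritParams repeat_library
#' @return A `repeat_library`.
#' @export
load_library <- function(fasta_path, metadata_path, priority = REPEAT_CLASSES) {
  seqs <- read_fasta(fasta_path)
  meta <- as_tibble(read.delim(metadata_path, stringsAsFactors = FALSE))
  no_meta <- setdiff(seqs$name, meta$name)
  if (length(no_meta)) {
    abort(paste("FASTA record(s) absent from metadata:",
                paste(no_meta, collapse = ", ")))
  }
  no_seq <- setdiff(meta$name, seqs$name)
  if (length(no_seq)) {
    abort(paste("metadata row(s) with no FASTA record:",
                paste(no_seq, collapse = ", ")))
  }
  meta <- meta[match(seqs$name, meta$name), ]
  meta$seq <- seqs$seq
  repeat_library(meta, priority = priority)
}

#' Write a repeat library back to FASTA + TSV
#'
#' Round trip with [load_library()] reproduces sequences and metadata
#' exactly.
#'
#' @param lib A `repeat_library`.
#' @param fasta_path,metadata_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_library <- function(lib, fasta_path, metadata_path) {
  write_fasta(lib, fasta_path)
  meta <- as.data.frame(lib[, c("name", "repclass", "subclass", "is_tandem",
                                "monomer_len", "te_part", "is_expanded")])
  write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Telomere reference record
#'
#' Builds the vertebrate telomere repeat reference as `n_units` copies of
#' `TTAGGG`. The record keeps `monomer_len = 6` while storing the expanded
#' run, and is flagged `is_expanded` to mark this documented exception to the
#' monomer-length invariant.
#'
#' @param n_units Number of TTAGGG units (>= 1); 20 mirrors the usual
#'   (TTAGGG)20 search reference.
#' @return A one-row `repeat_library` record tibble.
#' @export
build_telomere_reference <- function(n_units = 20L) {
  stopifnot_scalar_count(n_units, "n_units")
  tibble(
    name = "TEL", repclass = "TR", subclass = "telomere",
    is_tandem = TRUE, monomer_len = 6L, te_part = "none",
    is_expanded = TRUE,
    seq = strrep("TTAGGG", n_units)
  )
}

#' Duplicate a tandem consensus
#'
#' Doubles a tandem monomer head-to-tail so that every read-length window of
#' a long array, including windows spanning the monomer junction, occurs as a
#' contiguous substring of the reference. Coordinates reported against the
#' duplicated reference are reduced modulo `monomer_len` downstream.
#'
#' @param rec A one-row tandem library record.
#' @return The record with `seq` doubled and `is_expanded = TRUE`.
#' @export
duplicate_tandem_consensus <- function(rec) {
  if (nrow(rec) != 1L) abort("`rec` must be a single library record")
  if (!isTRUE(rec$is_tandem)) {
    abort(sprintf("record '%s' is not tandem; nothing to duplicate", rec$name))
  }
  rec$seq <- strrep(rec$seq, 2L)
  rec$is_expanded <- TRUE
  rec
}

# Alignment reference for one record: tandem monomers are expanded so the
# reference covers at least one junction and two read lengths; non-tandem
# records align as stored.
reference_seq <- function(rec, read_len = 37L) {
  if (!isTRUE(rec$is_tandem)) return(rec$seq)
  unit <- rec$seq  # expanded records keep their stored run as the unit
  target <- max(2L * nchar(unit), nchar(unit) + 2L * read_len)
  strrep(unit, ceiling(target / nchar(unit)))
}
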