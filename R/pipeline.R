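#' Read a pipeline configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers where possible, comma-separated lists become vectors. Keys
#' mirror the arguments of [run_pipeline()]'s config list.
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- list()
  for (p in kv) {
    val <- strsplit(p[2], "\\s*,\\s*")[[1]]
    num <- suppressWarnings(as.numeric(val))
    out[[p[1]]] <- if (!anyNA(num)) num else val
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stages in workflow order -- read cleaning, repeat
#' quantification, per-consensus coverage profiles (with enrichment-segment
#' calls), and, when contigs are supplied, tandem-array detection and the
#' co-occurrence screen -- writing a report bundle to `outdir`:
#' `composition.tsv`, `profiles/<name>.bedgraph` (+ `<name>.segments.tsv`),
#' `arrays.gff3`, `screen.tsv` and `run.log` (package version, configuration
#' hash, seed and every threshold used). Any stage error aborts with the
#' stage name.
#'
#' @param config Named list (or path to a [read_config()] file) with
#'   entries: `reads` (FASTQ path), `library_fasta`, `library_meta`,
#'   `outdir`; optional `contigs` (FASTA), `profile_consensus` (character
#'   vector of record names), `tr_families` (tandem families to scan,
#'   default all tandem records), `screen_tr_family`, `screen_min_monomers`,
#'   `screen_min_te_len`, `seed`, plus overrides for [qc_params()],
#'   [scoring_scheme()] and [tr_criteria()] fields.
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  cfg <- config
  need <- c("reads", "library_fasta", "library_meta", "outdir")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    abort(paste("config is missing:", paste(miss, collapse = ", ")))
  }
  for (p in c("reads", "library_fasta", "library_meta", "contigs")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      abort(sprintf("input path '%s' does not exist", cfg[[p]]))
    }
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  set.seed(seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  qc <- qc_params(window = cfg$qc_window %||% 4L,
                  min_mean_q = cfg$qc_min_q %||% 25,
                  min_len = cfg$qc_min_len %||% 30L)
  scheme <- scoring_scheme(min_score = cfg$min_score %||% 40L)
  trc <- tr_criteria(
    max_monomer_len = cfg$max_monomer_len %||% 2000L,
    min_array_len = cfg$min_array_len %||% 3000L,
    max_insert_gap = cfg$max_insert_gap %||% 50L,
    identity_threshold = cfg$identity_threshold %||% 75)

  log_path <- file.path(cfg$outdir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("chromoscan %s", as.character(packageVersion("chromoscan")))
  cfg_file <- tempfile()
  writeLines(paste(names(cfg), vapply(cfg, function(x)
    paste(x, collapse = ","), ""), sep = "="), cfg_file)
  logf("config_hash %s", unname(tools::md5sum(cfg_file)))
  logf("seed %d", seed)
  logf("qc window=%d min_mean_q=%g min_len=%d", qc$window, qc$min_mean_q,
       qc$min_len)
  logf("scoring match=%d mismatch=%d gap_open=%d gap_extend=%d min_score=%d min_aln_len=%d",
       scheme$match, scheme$mismatch, scheme$gap_open, scheme$gap_extend,
       scheme$min_score, scheme$min_aln_len)
  logf("tr_criteria max_monomer_len=%g min_array_len=%g max_insert_gap=%g identity_threshold=%g",
       trc$max_monomer_len, trc$min_array_len, trc$max_insert_gap,
       trc$identity_threshold)

  lib <- stage("library", load_library(cfg$library_fasta, cfg$library_meta))
  logf("library %d records", nrow(lib))

  raw <- stage("read_input", read_fastq(cfg$reads))
  cleaned <- stage("qc", clean_readset(raw, qc))
  st <- qc_stats(cleaned)
  logf("qc input=%d kept=%d removed=%.2f%%", st$n_input, st$n_kept,
       st$fraction_removed)

  comp <- stage("quantify", quantify(cleaned, lib, scheme))
  comp_path <- file.path(cfg$outdir, "composition.tsv")
  write_tsv_plain(comp, comp_path)
  logf("composition -> %s", comp_path)

  prof_dir <- file.path(cfg$outdir, "profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  profiles <- list()
  for (nm in cfg$profile_consensus %||% character()) {
    p <- stage(paste0("profile:", nm),
               profile_coverage(cleaned, lib[lib$name == nm, ], scheme))
    write_bedgraph(p, file.path(prof_dir, paste0(nm, ".bedgraph")))
    seg <- detect_enriched_segments(p,
      smooth_window = cfg$smooth_window %||% 101L,
      fold_threshold = cfg$fold_threshold %||% 3.0,
      min_segment_len = cfg$min_segment_len %||% 200L)
    write_tsv_plain(seg, file.path(prof_dir, paste0(nm, ".segments.tsv")))
    logf("profile %s: %d aligned reads, %d segment(s)", nm,
         attr(p, "n_aligned"), nrow(seg))
    profiles[[nm]] <- p
  }

  arrays <- screen <- NULL
  if (!is.null(cfg$contigs)) {
    contigs <- stage("contig_input", {
      x <- read_fasta(cfg$contigs)
      tibble(contig_id = x$name, seq = x$seq)
    })
    fams <- cfg$tr_families %||% lib$name[lib$is_tandem]
    arrays <- stage("tandem", purrr::map(fams, function(f) {
      find_tandem_arrays(contigs, lib, f, trc, scheme)
    }) |> list_rbind())
    gff <- file.path(cfg$outdir, "arrays.gff3")
    write_gff3(arrays, gff)
    logf("tandem arrays: %d -> %s", nrow(arrays), gff)

    cr <- screen_criteria(
      tr_family = cfg$screen_tr_family %||% fams[1],
      min_monomers = cfg$screen_min_monomers %||% 1L,
      min_te_fragment_len = cfg$screen_min_te_len %||% 400L)
    screen <- stage("screen", screen_batch(contigs, cr, lib, scheme, trc))
    scr_path <- file.path(cfg$outdir, "screen.tsv")
    write_tsv_plain(screen$results, scr_path)
    logf("screen %s: %d/%d positive -> %s", cr$tr_family,
         sum(screen$results$positive), nrow(screen$results), scr_path)
  } else {
    logf("tandem/screen skipped: no contigs supplied")
  }

  invisible(list(library = lib, qc_stats = st, composition = comp,
                 profiles = profiles, arrays = arrays, screen = screen,
                 outdir = cfg$outdir))
}
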