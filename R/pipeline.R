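# End-to-end orchestration: ingest -> counts -> mask -> events -> windows ->
# motifs -> QC, with per-reference partitioning and stable plain-text
# serialization.

#' Validate alignment/reference agreement before computation
#'
#' Hard failures (unknown reference names, no read-of-pair flags at all)
#' abort; soft findings (low expected event counts) are returned as warnings
#' in the report.
#'
#' @param aln alignment table, `"rims_sim"` object, or SAM/BAM path.
#' @param genome a [reference_set()].
#' @param cfg an [extraction_config()].
#' @return list with `n_records`, `references`, `warnings` (character vector,
#'   empty when clean).
#' @export
validate_inputs <- function(aln, genome, cfg = extraction_config()) {
  aln <- read_alignments(aln)
  unknown <- setdiff(unique(aln$rname), c(names(genome), "*"))
  if (length(unknown)) {
    stop("alignment references missing from the reference set: ",
         paste(unknown, collapse = ", "))
  }
  rp <- bitwAnd(aln$flag, 64L + 128L)
  if (nrow(aln) && !any(rp %in% c(64L, 128L))) {
    stop("no read carries a first/second-in-pair flag: input is not paired-end")
  }
  warnings <- character()
  bad <- sum(rp %in% c(0L, 192L))
  if (bad) warnings <- c(warnings, sprintf(
    "%d record(s) with neither/both read-of-pair flags will be dropped", bad))
  approx_depth <- sum(nchar(aln$seq)) / sum(nchar(genome))
  if (nrow(aln) && approx_depth < 5) warnings <- c(warnings, sprintf(
    "approximate coverage %.1fx is low; expect few foreground windows",
    approx_depth))
  list(n_records = nrow(aln), references = names(genome), warnings = warnings)
}

#' Run the full analysis on one alignment set
#'
#' Ingests alignments, accumulates filtered site counts, masks true-variant
#' positions, calls foreground/background event positions, harvests
#' strand-normalized context windows, and runs iterative motif discovery
#' independently per reference, plus the QC statistics (substitution
#' spectrum, imbalance folds, two-sample logo, abundance, and -- when a fully
#' methylated control is named -- the deamination-rate estimate).  The
#' control reference is excluded from motif discovery.
#'
#' @param aln alignment table, `"rims_sim"` object, or SAM/BAM path.
#' @param genome a [reference_set()] (or FASTA path).
#' @param extraction an [extraction_config()].
#' @param discovery a [discovery_config()].
#' @param control_ref optional name of a fully methylated spike-in reference.
#' @param keep_counts keep the (large) per-site count matrices in the result
#'   (default `FALSE`).
#' @return list of class `"rims_result"` with elements `events`, `windows`,
#'   `mask`, `motifs` (per-reference MotifResults, with a `ref` column),
#'   `spectrum`, `folds`, `context` (NCNNN table), `logo`, `abundance`,
#'   `deamination` (or `NULL`), `report`.
#' @export
rims_run <- function(aln, genome, extraction = extraction_config(),
                     discovery = discovery_config(), control_ref = NULL,
                     keep_counts = FALSE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_reference(genome)
  }
  aln <- read_alignments(aln)
  aln <- ingest_alignments(aln, extraction)
  ingest_report <- attr(aln, "report")
  sc <- accumulate_site_counts(aln, genome, extraction)
  mask <- compute_variant_mask(sc, genome, extraction)
  events <- call_event_positions(sc, genome, mask, extraction)
  windows <- harvest_windows(events, genome, extraction)
  discovery_refs <- setdiff(names(genome), control_ref)
  motifs <- list()
  for (rn in discovery_refs) {
    fg <- windows[windows$ref == rn & windows$label == "foreground", ,
                  drop = FALSE]
    bg <- windows[windows$ref == rn & windows$label == "background", ,
                  drop = FALSE]
    if (!nrow(fg) || !nrow(bg)) next
    res <- discover_all(fg, bg, discovery)
    if (nrow(res)) {
      res <- cbind(ref = rn, res, stringsAsFactors = FALSE)
      motifs[[rn]] <- res
    }
  }
  motifs <- if (length(motifs)) {
    out <- do.call(rbind, motifs); rownames(out) <- NULL; out
  } else cbind(ref = character(), .empty_motif_results())
  spectrum <- substitution_spectrum(sc, genome, extraction)
  folds <- imbalance_fold(spectrum)
  context <- context_spectrum(events, genome, extraction)
  fgw <- windows[windows$label == "foreground", , drop = FALSE]
  bgw <- windows[windows$label == "background", , drop = FALSE]
  logo <- if (nrow(fgw) && nrow(bgw)) two_sample_logo(fgw, bgw) else NULL
  abundance <- community_abundance(aln, genome, extraction)
  deamination <- if (!is.null(control_ref)) {
    estimate_deamination_rate(sc, genome, control_ref)
  } else NULL
  structure(list(
    events = events, windows = windows, mask = mask, motifs = motifs,
    spectrum = spectrum, folds = folds, context = context, logo = logo,
    abundance = abundance,
    deamination = deamination,
    counts = if (keep_counts) sc else NULL,
    report = list(ingest = as.list(ingest_report),
                  windows = as.list(attr(windows, "report")))
  ), class = "rims_result")
}

#' @export
print.rims_result <- function(x, ...) {
  cat("RIMS-seq analysis result\n")
  cat(sprintf("  events: %d foreground / %d background\n",
              sum(x$events$label == "foreground"),
              sum(x$events$label == "background")))
  if (nrow(x$motifs)) {
    cat("  motifs:\n")
    for (i in seq_len(nrow(x$motifs))) {
      cat(sprintf("    %s  %s (methylated offset %s, log10 p = %.1f)\n",
                  x$motifs$ref[i], x$motifs$motif[i],
                  x$motifs$methylated_offset[i], x$motifs$log10_p_corrected[i]))
    }
  } else cat("  motifs: none significant\n")
  invisible(x)
}

#' Run the full pipeline against files and write every artifact
#'
#' File-level wrapper over [rims_run()]: reads the inputs, writes events,
#' windows, variant mask, motifs, spectrum, folds, logo and abundance tables
#' as plain TSV/BED, plus a JSON run report and a manifest listing every
#' output with its MD5 checksum.  Identical inputs, configuration and seed
#' produce identical artifacts.
#'
#' @param aln alignment input (SAM/BAM path, table, or `"rims_sim"` object).
#' @param genome reference input ([reference_set()] or FASTA path).
#' @param out_prefix path prefix for every output file.
#' @param extraction an [extraction_config()].
#' @param discovery a [discovery_config()].
#' @param control_ref optional fully methylated control reference name.
#' @return (invisibly) the manifest data.frame.
#' @export
rims_run_all <- function(aln, genome, out_prefix,
                         extraction = extraction_config(),
                         discovery = discovery_config(),
                         control_ref = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_reference(genome)
  }
  validate_inputs(aln, genome, extraction)
  res <- rims_run(aln, genome, extraction, discovery, control_ref)
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr_tsv <- function(df, what) {
    p <- paste0(out_prefix, "_", what, ".tsv")
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[length(files) + 1L]] <<- p
  }
  wr_tsv(res$events, "events")
  wr_tsv(res$motifs, "motifs")
  wr_tsv(res$spectrum, "spectrum")
  wr_tsv(res$folds, "folds")
  wr_tsv(res$context, "context")
  if (!is.null(res$logo)) wr_tsv(res$logo, "logo")
  wr_tsv(res$abundance, "abundance")
  p <- paste0(out_prefix, "_mask.bed")
  write_bed(res$mask, p); files <- c(files, p)
  for (lab in c("foreground", "background")) {
    p <- paste0(out_prefix, "_windows_", substr(lab, 1L, 2L), ".txt")
    writeLines(res$windows$sequence[res$windows$label == lab], p)
    files <- c(files, p)
  }
  p <- paste0(out_prefix, "_report.json")
  jsonlite::write_json(
    c(res$report, list(deamination = res$deamination,
                       n_motifs = nrow(res$motifs))),
    p, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, p)
  manifest <- data.frame(file = basename(unlist(files)),
                         md5 = unname(tools::md5sum(unlist(files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, paste0(out_prefix, "_manifest.json"),
                       digits = NA)
  invisible(manifest)
}
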