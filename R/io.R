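# Plain-text serialization: SAM, FASTQ, TSV truth tables, BED.

#' Write an alignment table as SAM
#'
#' Records are sorted by reference and coordinate; the header carries
#' `@SQ` lines for every reference.
#'
#' @param x a `"rims_sim"` object or an alignment data.frame with the 11
#'   mandatory SAM columns (`qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`,
#'   `rnext`, `pnext`, `tlen`, `seq`, `qual`).
#' @param path output file.
#' @param genome [reference_set()] for the header (taken from `x` when it is a
#'   simulation object).
#' @export
write_sam <- function(x, path, genome = NULL) {
  if (inherits(x, "rims_sim")) {
    genome <- x$genome
    reads <- x$reads
  } else reads <- x
  stopifnot(!is.null(genome))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  ord <- order(match(reads$rname, names(genome)), reads$pos)
  reads <- reads[ord, , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
                  reads$cigar, reads$rnext, reads$pnext, reads$tlen,
                  reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into an alignment table
#'
#' Parses the 11 mandatory columns (optional tags are ignored).
#'
#' @param path SAM file.
#' @return list with `reads` (alignment data.frame) and `references` (named
#'   integer vector of `@SQ` lengths).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  sq <- lines[is_hdr & startsWith(lines, "@SQ")]
  refs <- setNames(
    as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)),
    sub(".*\tSN:([^\t]+).*", "\\1", sq)
  )
  body <- lines[!is_hdr]
  if (!length(body)) {
    return(list(reads = .empty_reads()$reads, references = refs))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1L), i)
  reads <- data.frame(
    qname = get(1L), flag = as.integer(get(2L)), rname = get(3L),
    pos = as.integer(get(4L)), mapq = as.integer(get(5L)), cigar = get(6L),
    rnext = get(7L), pnext = as.integer(get(8L)), tlen = as.integer(get(9L)),
    seq = get(10L), qual = get(11L), stringsAsFactors = FALSE
  )
  list(reads = reads, references = refs)
}

#' Read alignments from SAM, BAM, a simulation object or an alignment table
#'
#' BAM input requires the `Rsamtools` package.
#'
#' @param x path to a `.sam`/`.bam` file, a `"rims_sim"` object, or an
#'   alignment data.frame.
#' @return alignment data.frame.
#' @export
read_alignments <- function(x) {
  if (inherits(x, "rims_sim")) return(x$reads)
  if (is.data.frame(x)) return(x)
  stopifnot(is.character(x), length(x) == 1L, file.exists(x))
  if (grepl("\\.bam$", x, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("reading BAM requires the Rsamtools package")
    }
    b <- Rsamtools::scanBam(x, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
               "mrnm", "mpos", "isize", "seq", "qual")))[[1L]]
    return(data.frame(
      qname = b$qname, flag = b$flag, rname = as.character(b$rname),
      pos = b$pos, mapq = b$mapq, cigar = b$cigar,
      rnext = as.character(b$mrnm), pnext = b$mpos, tlen = b$isize,
      seq = as.character(b$seq), qual = as.character(b$qual),
      stringsAsFactors = FALSE
    ))
  }
  read_sam(x)$reads
}

#' Write simulated reads as paired FASTQ (Phred+33)
#'
#' Reads are written in their raw (sequencer) orientation: reverse-mapped
#' records are reverse-complemented back and their quality strings reversed.
#'
#' @param sim a `"rims_sim"` object.
#' @param prefix output prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @export
write_fastq <- function(sim, prefix) {
  reads <- sim$reads
  is_r1 <- bitwAnd(reads$flag, 64L) > 0L
  rev <- bitwAnd(reads$flag, 16L) > 0L
  raw_seq <- reads$seq
  raw_seq[rev] <- rc_bulk(raw_seq[rev])
  raw_qual <- reads$qual
  raw_qual[rev] <- vapply(strsplit(raw_qual[rev], "", fixed = TRUE),
                          function(q) paste(rev(q), collapse = ""),
                          character(1L))
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (i in 1:2) {
    sel <- if (i == 1L) is_r1 else !is_r1
    # mate order must agree between the two files
    ord <- order(reads$qname[sel])
    rec <- rbind(paste0("@", reads$qname[sel][ord], "/", i),
                 raw_seq[sel][ord], "+", raw_qual[sel][ord])
    writeLines(as.vector(rec), paths[i])
  }
  invisible(paths)
}

#' Write simulation truth tables
#'
#' Serializes the ground truth as TSVs (`sites`, `fragments`, `events`,
#' `variants`) plus a JSON parameter echo.
#'
#' @param sim a `"rims_sim"` object.
#' @param prefix output prefix.
#' @return character vector of the files written.
#' @export
write_truth <- function(sim, prefix) {
  tt <- sim$truth
  files <- character()
  wr <- function(df, what) {
    p <- paste0(prefix, "_", what, ".tsv")
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- c(files, wr(tt$sites, "sites"), wr(tt$fragments, "fragments"),
             wr(tt$events, "events"), wr(tt$variants, "variants"))
  pj <- paste0(prefix, "_params.json")
  jsonlite::write_json(c(tt$params, list(seed = tt$seed)), pj,
                       auto_unbox = TRUE, digits = NA, null = "null")
  c(files, pj)
}

#' Write a masked-position set as BED3
#'
#' @param mask data.frame with `ref` and `pos` (0-based) columns.
#' @param path output file.
#' @export
write_bed <- function(mask, path) {
  writeLines(sprintf("%s\t%d\t%d", mask$ref, mask$pos, mask$pos + 1L), path)
  invisible(path)
}
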