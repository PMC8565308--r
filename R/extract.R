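# Alignment ingestion and per-site substitution counting.
#
# SiteCounts is the pipeline's central accumulator: for every reference
# position, filtered base counts stratified by read-of-pair (R1/R2) and
# mapping strand (F/R).  The four cells are named R1F, R1R, R2F, R2R; base
# counts only include bases at or above the quality threshold, while depth
# counts every aligned base.

.CELLS <- c("R1F", "R1R", "R2F", "R2R")
.BASES <- c("A", "C", "G", "T")

#' Filter alignment records and annotate read-of-pair and strand
#'
#' Drops unmapped, mate-unmapped, secondary, supplementary and
#' duplicate-flagged records (when `read_filters` is on), records below the
#' mapping-quality threshold, and records that are not properly tagged as
#' exactly one of first/second-in-pair (counted in the report).
#'
#' @param aln alignment table (see [read_alignments()]).
#' @param cfg an [extraction_config()].
#' @return the accepted records with added columns `read1` (logical),
#'   `reverse` (logical) and `cell` (`"R1F"`, ...).  The numbers dropped per
#'   filter are attached as `attr(, "report")`.
#' @export
ingest_alignments <- function(aln, cfg = extraction_config()) {
  flag <- aln$flag
  report <- c(total = nrow(aln))
  drop_flags <- if (cfg$read_filters) {
    bitwAnd(flag, 4L) > 0L | bitwAnd(flag, 8L) > 0L |
      bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L |
      bitwAnd(flag, 1024L) > 0L
  } else bitwAnd(flag, 4L) > 0L
  bad_pairing <- bitwAnd(flag, 64L + 128L) %in% c(0L, 192L) & !drop_flags
  if (any(bad_pairing)) {
    warning(sum(bad_pairing), " record(s) with neither/both read-of-pair flags")
  }
  low_mapq <- is.na(aln$mapq) | aln$mapq < cfg$min_mapping_quality
  keep <- !drop_flags & !low_mapq & !bad_pairing
  report <- c(report,
              dropped_flags = sum(drop_flags),
              dropped_mapq = sum(low_mapq & !drop_flags),
              dropped_pairing = sum(bad_pairing & !drop_flags & !low_mapq),
              accepted = sum(keep))
  out <- aln[keep, , drop = FALSE]
  out$read1 <- bitwAnd(out$flag, 64L) > 0L
  out$reverse <- bitwAnd(out$flag, 16L) > 0L
  out$cell <- .CELLS[1L + (!out$read1) * 2L + out$reverse]
  attr(out, "report") <- report
  out
}

#' Accumulate filtered per-site substitution counts
#'
#' Walks every accepted read's aligned bases (CIGAR M/=/X; insertions and
#' clips skip query, deletions skip reference), ignoring the first sequencing
#' cycle of every read (the 5'-most raw base, i.e. the last aligned base of a
#' reverse-mapped read) when configured.  Bases at or above
#' `min_base_quality` are counted into the (read-of-pair, strand) cell; bases
#' below it contribute to depth only.  Positions whose reference base is N
#' carry no counts.
#'
#' @param aln alignment table; passed through [ingest_alignments()] first if
#'   it has not been already.
#' @param genome a [reference_set()].
#' @param cfg an [extraction_config()].
#' @return object of class `"site_counts"`: per reference, `counts`
#'   (positions x 16, columns `R1F_A` ... `R2R_T`) and `depth`
#'   (positions x 4).
#' @export
accumulate_site_counts <- function(aln, genome, cfg = extraction_config()) {
  if (is.null(aln$cell)) aln <- ingest_alignments(aln, cfg)
  unknown <- setdiff(unique(aln$rname), names(genome))
  if (length(unknown)) stop("alignments reference unknown sequence(s): ",
                            paste(unknown, collapse = ", "))
  refs <- list()
  for (rn in names(genome)) {
    sel <- which(aln$rname == rn)
    L <- nchar(genome[[rn]])
    sub <- aln[sel, , drop = FALSE]
    res <- cpp_pileup(sub$seq, sub$qual, sub$pos, sub$cigar,
                      match(sub$cell, .CELLS) - 1L,
                      sub$reverse, L, cfg$min_base_quality,
                      cfg$exclude_first_cycle)
    colnames(res$counts) <- paste(rep(.CELLS, each = 4L), .BASES, sep = "_")
    colnames(res$depth) <- .CELLS
    isN <- utf8ToInt(genome[[rn]]) == utf8ToInt("N")
    if (any(isN)) {
      res$counts[isN, ] <- 0L
      res$depth[isN, ] <- 0L
    }
    refs[[rn]] <- res
  }
  structure(list(refs = refs, cfg = cfg), class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat("SiteCounts over", length(x$refs), "reference(s):\n")
  for (rn in names(x$refs)) {
    cat(sprintf("  %s  (%d positions, %.0f filtered bases)\n", rn,
                nrow(x$refs[[rn]]$counts), sum(x$refs[[rn]]$counts)))
  }
  invisible(x)
}

#' Mask positions that look like true variants
#'
#' For each position, the two reference-orientation substitutions C->T (at
#' reference C) and G->A (at reference G) are tested with counts pooled over
#' read-of-pair and mapping strand; the position is masked when the alternate
#' count reaches `variant_mask_min_reads` and the alternate fraction of the
#' filtered depth exceeds `variant_mask_fraction`.  A true variant manifests
#' in all cells, so pooling maximizes mask power; rare deamination does not
#' reach 5% at normal depth.
#'
#' @param sc a `"site_counts"` object.
#' @param genome a [reference_set()].
#' @param cfg an [extraction_config()].
#' @return data.frame `ref`, `pos` (0-based), `substitution`, `alt_count`,
#'   `depth`.
#' @export
compute_variant_mask <- function(sc, genome, cfg = sc$cfg) {
  out <- list()
  for (rn in names(sc$refs)) {
    counts <- sc$refs[[rn]]$counts
    depth_all <- rowSums(sc$refs[[rn]]$depth)
    enc <- utf8ToInt(genome[[rn]])
    for (sub in list(c("C", "T"), c("G", "A"))) {
      at <- which(enc == utf8ToInt(sub[1L]))
      alt <- rowSums(counts[at, paste(.CELLS, sub[2L], sep = "_"),
                            drop = FALSE])
      dp <- depth_all[at]
      hit <- alt >= cfg$variant_mask_min_reads & dp > 0 &
        alt / dp > cfg$variant_mask_fraction
      if (any(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          ref = rn, pos = at[hit] - 1L,
          substitution = paste0(sub[1L], ">", sub[2L]),
          alt_count = alt[hit], depth = dp[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ref = character(), pos = integer(),
                      substitution = character(), alt_count = integer(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$ref, res$pos), , drop = FALSE]
}

#' Call candidate deamination event positions
#'
#' Foreground (the deamination signal classes): reference C with at least one
#' high-quality T on forward-mapped read 1 (methylated strand +), and
#' reference G with at least one high-quality A on forward-mapped read 2
#' (methylated strand -).  Background (the mirror classes, where deamination
#' cannot occur): G with A on read 1, and C with T on read 2.  Under
#' `count_orientation = "all_strands"`, both mapping strands of the stated
#' read-of-pair are pooled instead.  Masked positions are excluded; each
#' qualifying (position, strand, label) yields one event.
#'
#' @param sc a `"site_counts"` object.
#' @param genome a [reference_set()].
#' @param mask output of [compute_variant_mask()] (or `NULL`).
#' @param cfg an [extraction_config()].
#' @return data.frame `ref`, `pos` (0-based), `strand` (methylated strand),
#'   `label` (`"foreground"`/`"background"`), `support`.
#' @export
call_event_positions <- function(sc, genome, mask = NULL,
                                 cfg = sc$cfg) {
  classes <- data.frame(
    ref_base = c("C", "G", "G", "C"),
    alt_base = c("T", "A", "A", "T"),
    read = c("R1", "R2", "R1", "R2"),
    strand = c("+", "-", "-", "+"),
    label = c("foreground", "foreground", "background", "background"),
    stringsAsFactors = FALSE
  )
  out <- list()
  for (rn in names(sc$refs)) {
    counts <- sc$refs[[rn]]$counts
    enc <- utf8ToInt(genome[[rn]])
    masked <- if (is.null(mask)) integer() else mask$pos[mask$ref == rn]
    for (i in seq_len(nrow(classes))) {
      cl <- classes[i, ]
      cells <- if (cfg$count_orientation == "forward_only") {
        paste0(cl$read, "F")
      } else paste0(cl$read, c("F", "R"))
      at <- which(enc == utf8ToInt(cl$ref_base))
      supp <- rowSums(counts[at, paste(cells, cl$alt_base, sep = "_"),
                             drop = FALSE])
      hit <- supp >= 1L
      if (length(masked)) hit <- hit & !((at - 1L) %in% masked)
      if (any(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          ref = rn, pos = at[hit] - 1L, strand = cl$strand,
          label = cl$label, support = supp[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ref = character(), pos = integer(), strand = character(),
                      label = character(), support = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$ref, res$pos, res$label, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Harvest strand-normalized context windows around event positions
#'
#' Each event yields the `2 * window_flank + 1` bases of genomic context
#' centered on the event; minus-strand events are reverse-complemented so
#' that the putatively deaminated C sits at the center of every window.
#' Windows truncated by contig ends or containing N are dropped (counted in
#' the attached report).
#'
#' @param events output of [call_event_positions()].
#' @param genome a [reference_set()].
#' @param cfg an [extraction_config()].
#' @return data.frame `ref`, `pos`, `strand`, `label`, `sequence`, with a
#'   dropped-window report in `attr(, "report")`.
#' @export
harvest_windows <- function(events, genome, cfg = extraction_config()) {
  f <- cfg$window_flank
  out <- list()
  n_trunc <- 0L; n_amb <- 0L
  for (rn in unique(events$ref)) {
    ev <- events[events$ref == rn, , drop = FALSE]
    L <- nchar(genome[[rn]])
    ok <- ev$pos - f >= 0L & ev$pos + f <= L - 1L
    n_trunc <- n_trunc + sum(!ok)
    ev <- ev[ok, , drop = FALSE]
    if (!nrow(ev)) next
    w <- substring(genome[[rn]], ev$pos - f + 1L, ev$pos + f + 1L)
    minus <- ev$strand == "-"
    w[minus] <- rc_bulk(w[minus])
    amb <- grepl("N", w, fixed = TRUE)
    n_amb <- n_amb + sum(amb)
    ev <- ev[!amb, , drop = FALSE]
    ev$sequence <- w[!amb]
    out[[rn]] <- ev
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(ref = character(), pos = integer(), strand = character(),
               label = character(), support = integer(),
               sequence = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "report") <- c(truncated = n_trunc, ambiguous = n_amb)
  res
}
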