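# Damage/QC statistics: substitution spectra, R1/R2 imbalance folds, spike-in
# deamination-rate estimation, context spectra, two-sample logos, community
# abundance.

#' Per-read-of-pair substitution spectrum
#'
#' For each read-of-pair and each of the 12 substitution classes X->Y (in
#' reference orientation), the rate is the number of quality-passing Y bases
#' at reference-X positions divided by the quality-passing depth at those
#' positions.  Under the default `forward_only` orientation only
#' forward-mapped reads are counted; `all_strands` pools both mapping
#' strands.  All 12 classes are reported so damage other than deamination
#' (e.g. the G->T oxidation imbalance) is visible.
#'
#' @param sc a `"site_counts"` object.
#' @param genome a [reference_set()].
#' @param cfg an [extraction_config()].
#' @param restrict_ref optionally restrict to one reference (e.g. a spike-in
#'   control).
#' @return data.frame with 24 rows: `read`, `ref_base`, `alt_base`, `count`,
#'   `depth`, `rate` (`NA` where the class has zero depth).
#' @export
substitution_spectrum <- function(sc, genome, cfg = sc$cfg,
                                  restrict_ref = NULL) {
  refs <- if (is.null(restrict_ref)) names(sc$refs) else restrict_ref
  stopifnot(all(refs %in% names(sc$refs)))
  acc <- matrix(0, nrow = 4L, ncol = 16L,
                dimnames = list(.BASES, colnames(sc$refs[[1L]]$counts)))
  for (rn in refs) {
    counts <- sc$refs[[rn]]$counts
    enc <- utf8ToInt(genome[[rn]])
    for (x in .BASES) {
      at <- which(enc == utf8ToInt(x))
      if (length(at)) acc[x, ] <- acc[x, ] + colSums(counts[at, , drop = FALSE])
    }
  }
  cells_for <- function(read) {
    if (cfg$count_orientation == "forward_only") paste0(read, "F")
    else paste0(read, c("F", "R"))
  }
  rows <- list()
  for (read in c("R1", "R2")) {
    cells <- cells_for(read)
    for (x in .BASES) {
      depth <- sum(acc[x, paste(rep(cells, each = 4L), .BASES, sep = "_")])
      for (y in setdiff(.BASES, x)) {
        cnt <- sum(acc[x, paste(cells, y, sep = "_")])
        rows[[length(rows) + 1L]] <- data.frame(
          read = read, ref_base = x, alt_base = y, count = cnt, depth = depth,
          rate = if (depth > 0) cnt / depth else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "orientation") <- cfg$count_orientation
  out
}

#' R1/R2 imbalance fold per substitution class
#'
#' The deamination signature manifests as an elevated C->T rate on read 1
#' relative to read 2; the fold of that imbalance tracks the achieved
#' deamination level (from a few fold for short treatments to hundreds of
#' fold for long ones).
#'
#' @param spectrum output of [substitution_spectrum()].
#' @return data.frame with 12 rows: `ref_base`, `alt_base`, `rate_r1`,
#'   `rate_r2`, `fold` (`Inf` with `infinite = TRUE` when the R2 rate is
#'   zero).
#' @export
imbalance_fold <- function(spectrum) {
  r1 <- spectrum[spectrum$read == "R1", ]
  r2 <- spectrum[spectrum$read == "R2", ]
  key <- paste(r1$ref_base, r1$alt_base)
  stopifnot(identical(key, paste(r2$ref_base, r2$alt_base)))
  fold <- ifelse(r2$rate > 0, r1$rate / r2$rate, Inf)
  data.frame(ref_base = r1$ref_base, alt_base = r1$alt_base,
             rate_r1 = r1$rate, rate_r2 = r2$rate, fold = fold,
             infinite = is.finite(r1$rate) & !is.na(r2$rate) & r2$rate == 0,
             stringsAsFactors = FALSE)
}

# Wilson score interval for a binomial proportion
.wilson <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(0, 1))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Estimate the m5C deamination rate from a fully methylated control
#'
#' On a spike-in whose cytosines are all m5C (an XP12-style control), the C->T
#' rate on forward-mapped read 1 measures deamination plus sequencing error,
#' and the same rate on read 2 measures the error floor; their difference is
#' the background-subtracted per-base deamination rate.  The confidence
#' interval is a Newcombe hybrid of the two Wilson intervals.
#'
#' @param sc a `"site_counts"` object.
#' @param genome a [reference_set()].
#' @param control_ref name of the fully methylated control reference.
#' @param conf confidence level (default 0.95).
#' @return list with `estimate`, `ci_low`, `ci_high`, and the underlying
#'   counts (`ct_r1`, `depth_r1`, `ct_r2`, `depth_r2`).
#' @export
estimate_deamination_rate <- function(sc, genome, control_ref, conf = 0.95) {
  if (!control_ref %in% names(sc$refs)) {
    stop("control reference '", control_ref, "' not present in the alignments")
  }
  counts <- sc$refs[[control_ref]]$counts
  enc <- utf8ToInt(genome[[control_ref]])
  at <- which(enc == utf8ToInt("C"))
  x1 <- sum(counts[at, "R1F_T"])
  n1 <- sum(counts[at, paste0("R1F_", .BASES)])
  x2 <- sum(counts[at, "R2F_T"])
  n2 <- sum(counts[at, paste0("R2F_", .BASES)])
  if (n1 == 0 || n2 == 0) stop("no coverage on the control reference")
  p1 <- x1 / n1; p2 <- x2 / n2
  w1 <- .wilson(x1, n1, conf); w2 <- .wilson(x2, n2, conf)
  d <- p1 - p2
  list(estimate = d,
       ci_low = d - sqrt((p1 - w1[1L])^2 + (w2[2L] - p2)^2),
       ci_high = d + sqrt((w1[2L] - p1)^2 + (p2 - w2[1L])^2),
       ct_r1 = x1, depth_r1 = n1, ct_r2 = x2, depth_r2 = n2)
}

#' NCNNN context spectrum of foreground events
#'
#' For every 5-mer with C at position 2, the fraction of foreground events
#' whose strand-normalized genomic context equals that 5-mer.  Fractions sum
#' to 1 over the 256 contexts when at least one event is in range (events
#' with N in context or truncated by contig ends are excluded).
#'
#' @param x foreground-capable input: an event data.frame from
#'   [call_event_positions()], or a `"site_counts"` object (events are called
#'   with default settings).
#' @param genome a [reference_set()].
#' @param cfg an [extraction_config()] (used only when `x` is a
#'   `"site_counts"` object).
#' @return data.frame with 256 rows: `context`, `events`, `fraction`;
#'   `attr(, "n_events")` carries the total used.
#' @export
context_spectrum <- function(x, genome, cfg = extraction_config()) {
  events <- if (inherits(x, "site_counts")) {
    call_event_positions(x, genome, cfg = cfg)
  } else x
  ev <- events[events$label == "foreground", , drop = FALSE]
  ctx <- .event_contexts(ev, genome, before = 1L, after = 3L)
  g <- expand.grid(b1 = .BASES, b3 = .BASES, b4 = .BASES, b5 = .BASES,
                   stringsAsFactors = FALSE)
  all_ctx <- sort(paste0(g$b1, "C", g$b3, g$b4, g$b5))
  tab <- table(factor(ctx, levels = all_ctx))
  n <- sum(tab)
  out <- data.frame(context = all_ctx, events = as.integer(tab),
                    fraction = if (n > 0) as.integer(tab) / n else 0,
                    stringsAsFactors = FALSE)
  attr(out, "n_events") <- n
  out
}

# strand-normalized context strings with the event base `before` bases in:
# plus events take genome[pos - before, pos + after], minus events take the
# reverse complement of genome[pos - after, pos + before].  Out-of-range or
# ambiguous contexts are NA.
.event_contexts <- function(events, genome, before, after) {
  if (!nrow(events)) return(character())
  ctx <- rep(NA_character_, nrow(events))
  for (rn in unique(events$ref)) {
    sel <- which(events$ref == rn)
    L <- nchar(genome[[rn]])
    pos <- events$pos[sel]
    minus <- events$strand[sel] == "-"
    lo <- ifelse(minus, pos - after, pos - before)
    hi <- ifelse(minus, pos + before, pos + after)
    ok <- lo >= 0L & hi <= L - 1L
    s <- rep(NA_character_, length(sel))
    s[ok] <- substring(genome[[rn]], lo[ok] + 1L, hi[ok] + 1L)
    s[ok & minus] <- rc_bulk(s[ok & minus])
    ctx[sel] <- s
  }
  ctx[grepl("N", ctx, fixed = TRUE)] <- NA_character_
  ctx[!is.na(ctx)]
}

#' Fraction of foreground events in a given motif context
#'
#' The fraction of foreground events whose strand-normalized context matches
#' the motif with the event base at the stated (1-based) offset.  Events
#' whose context extends past a contig end are excluded from numerator and
#' denominator.
#'
#' @param events output of [call_event_positions()].
#' @param genome a [reference_set()].
#' @param motif IUPAC motif.
#' @param offset 1-based position of the event base within the motif.
#' @return list with `fraction`, `matched`, `total`.
#' @export
motif_context_fraction <- function(events, genome, motif, offset) {
  k <- nchar(motif)
  stopifnot(offset >= 1L, offset <= k)
  ev <- events[events$label == "foreground", , drop = FALSE]
  ctx <- .event_contexts(ev, genome, before = offset - 1L, after = k - offset)
  if (!length(ctx)) return(list(fraction = NA_real_, matched = 0L, total = 0L))
  matched <- sum(vapply(ctx, function(s) iupac_matches(motif, s, 0L),
                        logical(1L), USE.NAMES = FALSE))
  list(fraction = matched / length(ctx), matched = matched,
       total = length(ctx))
}

#' Two-sample sequence logo matrix
#'
#' Position-specific base composition differences between foreground and
#' background windows over the central +/- `flank` positions (the event base
#' itself excluded).  Each (position, base) cell is tested with a two-sided
#' two-proportion z-test (pooled standard error, no continuity correction, no
#' multiplicity correction), flagged significant at `alpha`.
#'
#' @param windows_fg,windows_bg window sets (character vectors or data.frames
#'   from [harvest_windows()]); must be at least `2 * flank + 1` wide.
#' @param flank positions considered on each side of the center (default 7).
#' @param alpha significance level (default 0.01).
#' @return data.frame with `8 * flank` rows: `position` (relative to center),
#'   `base`, `fg_prop`, `bg_prop`, `diff`, `p_value`, `significant`.
#' @export
two_sample_logo <- function(windows_fg, windows_bg, flank = 7L, alpha = 0.01) {
  fg <- .window_seqs(windows_fg)
  bg <- .window_seqs(windows_bg)
  if (!length(fg) || !length(bg)) stop("both window sets must be non-empty")
  W <- nchar(fg[1L])
  stopifnot(W >= 2L * flank + 1L, nchar(bg[1L]) == W)
  center <- (W + 1L) %/% 2L
  sub_fg <- substr(fg, center - flank, center + flank)
  sub_bg <- substr(bg, center - flank, center + flank)
  sub_fg <- sub_fg[!grepl("N", sub_fg, fixed = TRUE)]
  sub_bg <- sub_bg[!grepl("N", sub_bg, fixed = TRUE)]
  if (!length(sub_fg) || !length(sub_bg)) stop("no windows left after N filter")
  Mf <- .encode_windows(sub_fg)
  Mb <- .encode_windows(sub_bg)
  rel <- setdiff(-flank:flank, 0L)
  rows <- list()
  for (p in rel) {
    col <- flank + 1L + p
    for (b in .BASES) {
      bit <- IUPAC_MASK[[b]]
      x1 <- sum(Mf[, col] == bit); n1 <- nrow(Mf)
      x2 <- sum(Mb[, col] == bit); n2 <- nrow(Mb)
      p1 <- x1 / n1; p2 <- x2 / n2
      pp <- (x1 + x2) / (n1 + n2)
      se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
      pv <- if (se > 0) 2 * pnorm(-abs(p1 - p2) / se) else 1
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, base = b, fg_prop = p1, bg_prop = p2, diff = p1 - p2,
        p_value = pv, significant = pv < alpha, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "test") <- "two-proportion z-test, pooled SE, two-sided"
  out
}

#' Relative abundance of references in a (community) alignment set
#'
#' Abundance of each reference is its accepted primary-aligned read count
#' normalized to the total accepted reads.  Downstream extraction and
#' discovery are then run independently per reference (windows are never
#' pooled across references).
#'
#' @param aln alignment table, `"rims_sim"` object, or SAM/BAM path.
#' @param genome a [reference_set()] (defines the reference universe).
#' @param cfg an [extraction_config()].
#' @return data.frame `ref`, `reads`, `abundance`.
#' @export
community_abundance <- function(aln, genome, cfg = extraction_config()) {
  aln <- read_alignments(aln)
  if (is.null(aln$cell)) aln <- ingest_alignments(aln, cfg)
  counts <- table(factor(aln$rname, levels = names(genome)))
  total <- sum(counts)
  data.frame(ref = names(genome), reads = as.integer(counts),
             abundance = if (total > 0) as.integer(counts) / total else 0,
             stringsAsFactors = FALSE)
}
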