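# De-novo discovery of IUPAC motifs over-represented in foreground vs
# background context windows.
#
# Search strategy (staged, deterministic):
#   1. seed enumeration: every exact k-mer (k in the configured length range)
#      occurring as a center-spanning substring of a foreground window is
#      scored exactly; the top seed_pool_size seeds are retained.  True motifs
#      span the window center because the methylated C is at the center by
#      construction.
#   2. hill-climbing from each retained seed: repeatedly apply the single
#      best-improving edit among (generalize one position to a degenerate
#      superset symbol within the degeneracy budgets, trim one terminal
#      position while longer than the minimum) until no edit improves the
#      Fisher p.  Scoring scans all offsets of all windows, so the statistic
#      stays consistent between foreground and background.
#   3. the best candidate over everything evaluated is reported iff its
#      Bonferroni-corrected p (factor = closed-form candidate-space size)
#      beats the threshold.  Ties break to lower p, then shorter motif, then
#      lexicographic order.
#
# All p-values are carried in log10 space: real signals sit far below
# double-precision underflow.

.window_seqs <- function(windows) {
  if (is.data.frame(windows)) windows$sequence else as.character(windows)
}

.encode_windows <- function(seqs) {
  n <- length(seqs)
  if (!n) return(matrix(integer(), 0L, 0L))
  W <- nchar(seqs[1L])
  if (any(nchar(seqs) != W)) stop("windows must all have the same width")
  enc <- .text_char_lut[utf8ToInt(paste(seqs, collapse = ""))]
  if (anyNA(enc)) stop("windows must be over {A,C,G,T,N}")
  matrix(enc, nrow = n, ncol = W, byrow = TRUE)
}

#' Count occurrences of an IUPAC motif in a window set
#'
#' Slides the motif over every offset of every window (overlapping matches
#' all count).  Masked (`N`) window positions never match.
#'
#' @param motif IUPAC string.
#' @param windows character vector of equal-width windows, or a window
#'   data.frame from [harvest_windows()].
#' @return list with `occurrences`, `scan_positions`
#'   (`sum over windows of (width - k + 1)`), and `offset_histogram`, keyed by
#'   distance from occurrence start to the window center.
#' @export
count_occurrences <- function(motif, windows) {
  seqs <- .window_seqs(windows)
  m <- iupac_mask(motif)
  if (!length(seqs)) {
    return(list(occurrences = 0, scan_positions = 0,
                offset_histogram = integer()))
  }
  enc <- .encode_windows(seqs)
  if (length(m) > ncol(enc)) stop("motif longer than windows")
  sc <- cpp_motif_scan(enc, m)
  center0 <- (ncol(enc) - 1L) %/% 2L
  hist <- sc$hist
  names(hist) <- center0 - (seq_along(hist) - 1L)
  list(occurrences = sc$occurrences,
       scan_positions = nrow(enc) * (ncol(enc) - length(m) + 1L),
       offset_histogram = hist)
}

#' One-sided Fisher exact enrichment p-value, in log10 space
#'
#' Tests the 2x2 table `[[fg_occ, fg_scan - fg_occ], [bg_occ, bg_scan -
#' bg_occ]]` against the alternative that the foreground occurrence rate is
#' greater, i.e. the hypergeometric upper tail.  Computed in log space so that
#' p-values far below double underflow (log10 p of -1000 and beyond) remain
#' exact.
#'
#' @param fg_occ,fg_scan foreground occurrences and scan positions.
#' @param bg_occ,bg_scan background occurrences and scan positions.
#' @return log10 of the one-sided p-value.
#' @export
score_motif <- function(fg_occ, fg_scan, bg_occ, bg_scan) {
  if (any(fg_scan <= 0) || any(bg_scan <= 0)) stop("zero scan positions")
  stopifnot(all(fg_occ <= fg_scan), all(bg_occ <= bg_scan),
            all(fg_occ >= 0), all(bg_occ >= 0))
  phyper(fg_occ - 1, fg_scan, bg_scan, fg_occ + bg_occ,
         lower.tail = FALSE, log.p = TRUE) / log(10)
}

# ---------------------------------------------------------------------------
# search internals

.mask_to_motif <- function(masks) paste(.MASK_TO_CHAR[masks + 1L], collapse = "")

.budget_ok <- function(masks, cfg) {
  d <- MASK_POPCOUNT[masks + 1L]
  sum(d == 2L) <= cfg$budget_2fold && sum(d == 3L) <= cfg$budget_3fold &&
    sum(d == 4L) <= cfg$budget_n &&
    masks[1L] != 15L && masks[length(masks)] != 15L
}

.neighbors <- function(masks, cfg) {
  k <- length(masks)
  out <- list()
  for (j in seq_len(k)) {
    for (s in .SUPERSETS[[masks[j] + 1L]]) {
      cand <- masks
      cand[j] <- s
      if (.budget_ok(cand, cfg)) out[[length(out) + 1L]] <- cand
    }
  }
  if (k > cfg$min_motif_length) {
    for (cand in list(masks[-1L], masks[-k])) {
      if (.budget_ok(cand, cfg)) out[[length(out) + 1L]] <- cand
    }
  }
  out
}

# evaluate (and memoize) one motif against encoded fg/bg window matrices
.eval_motif <- function(masks, fgM, bgM, memo) {
  key <- .mask_to_motif(masks)
  if (!is.null(memo[[key]])) return(memo[[key]])
  k <- length(masks)
  fg_scan <- nrow(fgM) * (ncol(fgM) - k + 1L)
  bg_scan <- nrow(bgM) * (ncol(bgM) - k + 1L)
  f <- cpp_motif_scan(fgM, masks)
  b <- cpp_motif_scan(bgM, masks)
  res <- list(motif = key, masks = masks,
              fg_occ = f$occurrences, fg_scan = fg_scan,
              bg_occ = b$occurrences, bg_scan = bg_scan,
              hist = f$hist,
              lp = score_motif(f$occurrences, fg_scan, b$occurrences, bg_scan))
  memo[[key]] <- res
  res
}

.climb <- function(masks, fgM, bgM, cfg, memo, max_steps = 64L) {
  cur <- .eval_motif(masks, fgM, bgM, memo)
  for (step in seq_len(max_steps)) {
    best <- NULL
    for (cand in .neighbors(cur$masks, cfg)) {
      r <- .eval_motif(cand, fgM, bgM, memo)
      if (is.null(best) || r$lp < best$lp) best <- r
    }
    if (is.null(best) || best$lp >= cur$lp) break
    cur <- best
  }
  cur
}

# assign the methylated offset from the foreground occurrence-start histogram
.methylated_offset <- function(res, center0) {
  hist <- res$hist
  if (!length(hist) || all(hist == 0L)) {
    return(list(offset = NA_integer_, unresolved = TRUE))
  }
  start0 <- which.max(hist) - 1L
  off <- center0 - start0 + 1L  # 1-based position within the motif
  k <- length(res$masks)
  if (off < 1L || off > k || bitwAnd(res$masks[off], 2L) == 0L) {
    return(list(offset = NA_integer_, unresolved = TRUE))
  }
  list(offset = off, unresolved = FALSE)
}

.motif_result_row <- function(res, center0, log10_M, rank) {
  off <- .methylated_offset(res, center0)
  data.frame(
    motif = res$motif,
    methylated_offset = off$offset,
    offset_unresolved = off$unresolved,
    fg_occurrences = res$fg_occ,
    fg_scan_positions = res$fg_scan,
    bg_occurrences = res$bg_occ,
    bg_scan_positions = res$bg_scan,
    log10_p_raw = res$lp,
    log10_p_corrected = min(res$lp + log10_M, 0),
    rank = rank,
    stringsAsFactors = FALSE
  )
}

.empty_motif_results <- function() {
  data.frame(motif = character(), methylated_offset = integer(),
             offset_unresolved = logical(), fg_occurrences = numeric(),
             fg_scan_positions = numeric(), bg_occurrences = numeric(),
             bg_scan_positions = numeric(), log10_p_raw = numeric(),
             log10_p_corrected = numeric(), rank = integer(),
             stringsAsFactors = FALSE)
}

#' Discover the single most enriched motif
#'
#' Runs the staged seed-and-climb search (see the package vignette) and
#' returns the best candidate if its Bonferroni-corrected p-value beats
#' `cfg$p_threshold`, otherwise `NULL` (the absence of a motif is a normal
#' outcome).
#'
#' @param windows_fg,windows_bg foreground and background window sets
#'   (character vectors of equal-width sequences, or data.frames from
#'   [harvest_windows()]).
#' @param cfg a [discovery_config()].
#' @param rank discovery iteration index recorded in the result.
#' @return one-row data.frame (a MotifResult) or `NULL`.
#' @export
discover_one <- function(windows_fg, windows_bg, cfg = discovery_config(),
                         rank = 1L) {
  fg <- .window_seqs(windows_fg)
  bg <- .window_seqs(windows_bg)
  if (length(fg) < cfg$min_foreground_windows) {
    warning("only ", length(fg), " foreground windows (need ",
            cfg$min_foreground_windows, "); skipping discovery")
    return(NULL)
  }
  if (!length(bg)) stop("motif discovery requires a background window set")
  fgM <- .encode_windows(fg)
  bgM <- .encode_windows(bg)
  if (ncol(fgM) != ncol(bgM)) stop("foreground/background widths differ")
  W <- ncol(fgM)
  center0 <- (W - 1L) %/% 2L
  memo <- new.env(parent = emptyenv())

  # stage 1: exact center-spanning seeds
  seeds <- character()
  seed_lp <- numeric()
  for (k in cfg$min_motif_length:min(cfg$max_motif_length, W)) {
    starts_center <- max(1L, center0 + 1L - k + 1L):min(center0 + 1L, W - k + 1L)
    cand <- unique(unlist(lapply(starts_center, function(st)
      substring(fg, st, st + k - 1L))))
    cand <- cand[!grepl("N", cand, fixed = TRUE)]
    if (!length(cand)) next
    starts_all <- seq_len(W - k + 1L)
    sub_fg <- unlist(lapply(starts_all, function(st) substring(fg, st, st + k - 1L)))
    sub_bg <- unlist(lapply(starts_all, function(st) substring(bg, st, st + k - 1L)))
    occ_fg <- tabulate(match(sub_fg, cand), nbins = length(cand))
    occ_bg <- tabulate(match(sub_bg, cand), nbins = length(cand))
    lp <- score_motif(occ_fg, length(fg) * length(starts_all),
                      occ_bg, length(bg) * length(starts_all))
    seeds <- c(seeds, cand)
    seed_lp <- c(seed_lp, lp)
  }
  if (!length(seeds)) return(NULL)
  ord <- order(seed_lp, nchar(seeds), seeds)
  seeds <- head(seeds[ord], cfg$seed_pool_size)

  # stage 2: greedy hill-climbing from every retained seed
  for (s in seeds) .climb(iupac_mask(s), fgM, bgM, cfg, memo)

  # stage 3: global best over everything evaluated, Bonferroni-corrected
  all_res <- as.list(memo)
  lp <- vapply(all_res, `[[`, numeric(1L), "lp")
  nm <- vapply(all_res, `[[`, character(1L), "motif")
  best <- all_res[[order(lp, nchar(nm), nm)[1L]]]
  log10_M <- log10(bonferroni_factor(cfg))
  if (best$lp + log10_M >= log10(cfg$p_threshold)) return(NULL)
  if (best$fg_occ / best$fg_scan <= best$bg_occ / best$bg_scan) return(NULL)
  .motif_result_row(best, center0, log10_M, rank)
}

#' Mask all occurrences of a motif in a window set
#'
#' Matched positions are replaced by `N` (which matches no pattern symbol,
#' including `N`), preserving window coordinates for offset histograms;
#' windows whose center becomes masked are removed.  Applied to foreground
#' and background alike between discovery iterations.
#'
#' @param windows character vector or window data.frame.
#' @param motif IUPAC string.
#' @return the window set with occurrences masked and center-masked windows
#'   removed (same type as the input).
#' @export
mask_motif <- function(windows, motif) {
  seqs <- .window_seqs(windows)
  if (!length(seqs)) return(windows)
  m <- iupac_mask(motif)
  k <- length(m)
  enc <- .encode_windows(seqs)
  sc <- cpp_motif_scan(enc, m, collect_positions = TRUE)
  if (length(sc$window)) {
    pad <- strrep("N", k)
    for (i in seq_along(sc$window)) {
      w <- sc$window[i]; st <- sc$start[i] + 1L
      substr(seqs[w], st, st + k - 1L) <- pad
    }
  }
  center <- (nchar(seqs[1L]) + 1L) %/% 2L
  keep <- substr(seqs, center, center) != "N"
  if (is.data.frame(windows)) {
    windows$sequence <- seqs
    windows[keep, , drop = FALSE]
  } else seqs[keep]
}

#' Discover all significantly enriched motifs by mask-and-repeat
#'
#' Repeatedly runs [discover_one()]; after each hit, every occurrence of the
#' found motif is masked out of both window sets and the search is repeated,
#' until no significant motif remains or `max_iterations` is reached.
#'
#' @inheritParams discover_one
#' @return data.frame of MotifResults ordered by discovery rank (zero rows if
#'   nothing is significant).
#' @export
discover_all <- function(windows_fg, windows_bg, cfg = discovery_config()) {
  results <- list()
  fg <- windows_fg
  bg <- windows_bg
  for (it in seq_len(cfg$max_iterations)) {
    res <- discover_one(fg, bg, cfg, rank = it)
    if (is.null(res)) break
    results[[it]] <- res
    fg <- mask_motif(fg, res$motif)
    bg <- mask_motif(bg, res$motif)
    if (!length(.window_seqs(fg))) break
  }
  if (!length(results)) return(.empty_motif_results())
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  out
}
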