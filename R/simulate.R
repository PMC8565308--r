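# Synthetic paired-end library simulator carrying the RIMS-seq damage
# signature.
#
# The generative model, per fragment (sonicated molecule):
#   * the template strand is the strand whose native orientation read 1
#     reports (Bernoulli 1/2);
#   * every annotated methylated site on the template strand is methylated on
#     this molecule with probability beta (independent per molecule x site);
#   * a methylated C deaminates to T with probability d_m5c (mutagenic: the
#     molecule is still amplified and sequenced);
#   * every unmethylated template-strand C deaminates to U with probability
#     d_c (blocking: one or more U drops the whole molecule);
#   * only the template strand is ever damaged.
#
# In SAM reference orientation this yields the documented signature: plus
# template molecules show C->T on forward-mapped read 1, minus-template
# molecules show G->A on forward-mapped read 2, and the mirror classes stay
# clean as long as mates do not overlap.

#' Deamination model parameters
#'
#' @param d_m5c per-base probability that an m5C on the template strand
#'   deaminates to T (mutagenic).  A 3 h heat-alkaline treatment typically
#'   achieves about 0.3%.
#' @param d_c per-base probability that an unmethylated C deaminates to U
#'   (blocking; the molecule is dropped).  m5C deaminates 1.5-3x faster than
#'   C, so `d_c` is usually set below `d_m5c`.
#' @return a list of class `"deamination_model"`.
#' @export
deamination_model <- function(d_m5c = 0.003, d_c = 0.001) {
  stopifnot(d_m5c >= 0, d_m5c <= 1, d_c >= 0, d_c <= 1)
  structure(list(d_m5c = d_m5c, d_c = d_c), class = "deamination_model")
}

#' Simulate fragment skeletons
#'
#' Fragment starts are uniform over the valid range; lengths are
#' Normal(insert_mean, insert_sd) rounded and truncated to
#' `[min_length, reference length]`, where `min_length` is `2 * read_length`
#' for non-overlapping mates (the default) or `read_length` when overlap is
#' allowed.  The template strand is Bernoulli(1/2).  Fragments never wrap:
#' genomes are treated as linear.
#'
#' @param genome single-entry [reference_set()].
#' @param n_fragments number of fragments.
#' @param insert_mean,insert_sd insert-size distribution (bases).
#' @param read_length intended downstream read length (default 100).
#' @param allow_overlap permit mates to overlap (fragments down to one read
#'   length).
#' @param seed optional RNG seed.
#' @return data.frame with columns `ref`, `start`, `end` (0-based half-open),
#'   `strand` (template strand).
#' @export
simulate_fragments <- function(genome, n_fragments, insert_mean = 300,
                               insert_sd = 30, read_length = 100L,
                               allow_overlap = FALSE, seed = NULL) {
  stopifnot(length(genome) == 1L, n_fragments >= 0L)
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(genome[[1L]])
  min_len <- if (allow_overlap) read_length else 2L * read_length
  if (L < min_len) stop("reference shorter than the minimum insert (", min_len, ")")
  n <- as.integer(n_fragments)
  len <- as.integer(pmin(pmax(round(rnorm(n, insert_mean, insert_sd)), min_len), L))
  start <- as.integer(floor(runif(n) * (L - len + 1L)))
  data.frame(ref = rep(names(genome), length.out = n), start = start,
             end = start + len,
             strand = ifelse(runif(n) < 0.5, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Apply deamination damage to a single fragment
#'
#' Reference implementation of the per-molecule damage semantics (see the
#' package vignette); the bulk simulator applies the same model in vectorized
#' form.  Positions are walked on the template strand in its native
#' orientation: an annotated methylated site is methylated with probability
#' beta and, if methylated, converts C to T with probability `d_m5c`; any
#' other (unmethylated) C converts to U with probability `d_c`, which marks
#' the fragment as dropped.
#'
#' @param fragment one row of [simulate_fragments()] output (or a list with
#'   `ref`, `start`, `end`, `strand`).
#' @param genome the [reference_set()] the fragment lies on.
#' @param site_table output of [annotate_methylated_sites()].
#' @param model a [deamination_model()].
#' @param seed optional RNG seed.
#' @return list with `ref`, `start`, `end`, `strand`, `template` (damaged
#'   template sequence, native orientation, possibly containing `U`),
#'   `events` (data.frame: `pos` 0-based reference position, `kind`), and
#'   `dropped`.
#' @export
apply_deamination <- function(fragment, genome, site_table, model,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- fragment$ref; s <- fragment$start; e <- fragment$end
  strand <- fragment$strand
  stopifnot(ref %in% names(genome), s >= 0L, e <= nchar(genome[[ref]]))
  plus_seg <- substr(genome[[ref]], s + 1L, e)
  template <- if (strand == "+") plus_seg else rc_concrete(plus_seg)
  tmpl <- strsplit(template, "", fixed = TRUE)[[1L]]
  n <- length(tmpl)
  # reference position of template index i (1-based i)
  refpos <- if (strand == "+") s + seq_len(n) - 1L else e - seq_len(n)
  st <- site_table[site_table$ref == ref & site_table$strand == strand &
                     site_table$pos >= s & site_table$pos < e, , drop = FALSE]
  is_site <- refpos %in% st$pos
  beta <- numeric(n)
  beta[is_site] <- st$beta[match(refpos[is_site], st$pos)]
  methylated <- is_site & runif(n) < beta
  ct <- methylated & tmpl == "C" & runif(n) < model$d_m5c
  cu <- !methylated & tmpl == "C" & runif(n) < model$d_c
  tmpl[ct] <- "T"
  tmpl[cu] <- "U"
  events <- rbind(
    if (any(ct)) data.frame(pos = refpos[ct], kind = "m5C>T",
                            stringsAsFactors = FALSE),
    if (any(cu)) data.frame(pos = refpos[cu], kind = "C>U",
                            stringsAsFactors = FALSE)
  )
  if (is.null(events)) events <- data.frame(pos = integer(), kind = character(),
                                            stringsAsFactors = FALSE)
  list(ref = ref, start = s, end = e, strand = strand,
       template = paste(tmpl, collapse = ""), events = events,
       dropped = any(cu))
}

#' Emit a paired-end read pair from a (damaged) fragment
#'
#' Read 1 is the first `read_length` bases of the damaged template in its
#' native orientation; read 2 is the reverse complement of the template's
#' last `read_length` bases.  Per-base sequencing errors are applied
#' independently (uniform over the other three bases) with constant Phred
#' base quality.  Returns `NULL` for dropped fragments (a U blocks
#' amplification).
#'
#' @param fragment output of [apply_deamination()].
#' @param read_length read length.
#' @param error_rate per-base sequencing error rate.
#' @param base_quality constant Phred quality (default 37).
#' @param seed optional RNG seed.
#' @return list with `r1`, `r2` (each: `name`, `read` raw read sequence,
#'   `qual`) and `sam` (data.frame of two idealized SAM records), or `NULL`
#'   if the fragment was dropped.
#' @export
emit_read_pair <- function(fragment, read_length = 100L, error_rate = 0,
                           base_quality = 37L, seed = NULL) {
  if (isTRUE(fragment$dropped)) return(NULL)
  if (!is.null(seed)) set.seed(seed)
  len <- fragment$end - fragment$start
  if (len < read_length) stop("fragment shorter than the read length")
  tmpl <- fragment$template
  r1 <- substr(tmpl, 1L, read_length)
  r2 <- rc_concrete(substr(tmpl, nchar(tmpl) - read_length + 1L, nchar(tmpl)))
  add_err <- function(x) {
    k <- rbinom(1L, read_length, error_rate)
    if (k > 0L) {
      at <- sample.int(read_length, k)
      for (i in at) {
        cur <- substr(x, i, i)
        substr(x, i, i) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
    x
  }
  r1 <- add_err(r1); r2 <- add_err(r2)
  qual <- strrep(intToUtf8(base_quality + 33L), read_length)
  nm <- sprintf("%s:%d-%d", fragment$ref, fragment$start, fragment$end)
  plus <- fragment$strand == "+"
  # rows ordered leftmost-first; SAM SEQ is stored in reference orientation,
  # so reverse-mapped reads are reverse-complemented back
  sam <- data.frame(
    qname = nm,
    flag = if (plus) c(99L, 147L) else c(163L, 83L),
    rname = fragment$ref,
    pos = c(fragment$start, fragment$end - read_length) + 1L,
    mapq = 60L,
    cigar = paste0(read_length, "M"),
    rnext = "=",
    pnext = c(fragment$end - read_length, fragment$start) + 1L,
    tlen = c(len, -len),
    seq = if (plus) c(r1, rc_concrete(r2)) else c(r2, rc_concrete(r1)),
    qual = qual,
    stringsAsFactors = FALSE
  )
  list(r1 = list(name = paste0(nm, "/1"), read = r1, qual = qual),
       r2 = list(name = paste0(nm, "/2"), read = r2, qual = qual),
       sam = sam)
}

# concrete-alphabet reverse complement (keeps U -> A bookkeeping out: U has no
# complement here; callers never reverse-complement dropped templates)
rc_concrete <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# fast vectorized reverse complement for large character vectors
rc_bulk <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Inject germline C->T / G->A variants
#'
#' Chooses reference C or G positions (avoiding annotated methylated sites so
#' that every emitted mismatch has a unique cause).  Each fragment overlapping
#' a variant position carries the alternate allele with probability
#' `allele_fraction`, on both strands of the molecule, so the variant is
#' visible in read 1 and read 2 classes alike -- which is what the 5%/5-read
#' mask must catch.
#'
#' @param genome a [reference_set()].
#' @param n_variants number of variant positions.
#' @param allele_fraction per-molecule carrier probability in `(0, 1]`.
#' @param exclude data.frame with `ref`/`pos` columns (e.g. a site table) of
#'   positions to avoid.
#' @param seed optional RNG seed.
#' @return data.frame `ref`, `pos` (0-based), `ref_base`, `alt_base`,
#'   `allele_fraction`.
#' @export
inject_variants <- function(genome, n_variants, allele_fraction = 0.5,
                            exclude = NULL, seed = NULL) {
  stopifnot(allele_fraction > 0, allele_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (n_variants == 0L) {
    return(data.frame(ref = character(), pos = integer(),
                      ref_base = character(), alt_base = character(),
                      allele_fraction = numeric(), stringsAsFactors = FALSE))
  }
  out <- list()
  for (rn in names(genome)) {
    enc <- utf8ToInt(genome[[rn]])
    cand <- which(enc == 67L | enc == 71L) - 1L
    if (!is.null(exclude)) {
      cand <- setdiff(cand, exclude$pos[exclude$ref == rn])
    }
    out[[rn]] <- data.frame(ref = rn, pos = cand,
                            ref_base = intToUtf8(enc[cand + 1L], multiple = TRUE),
                            stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, out)
  take <- cand[sample.int(nrow(cand), min(n_variants, nrow(cand))), , drop = FALSE]
  take$alt_base <- ifelse(take$ref_base == "C", "T", "A")
  take$allele_fraction <- allele_fraction
  rownames(take) <- NULL
  take
}

# ---------------------------------------------------------------------------
# vectorized per-reference engine

# damage + dropout for a table of fragments on one reference sequence
.sim_damage_vec <- function(frags, seq_string, sites, d_m5c, d_c) {
  n <- nrow(frags)
  cum <- .cum_base_counts(seq_string, c("C", "G"))
  n_meth <- integer(n)
  ev_frag <- integer(0); ev_pos <- integer(0); ev_strand <- character(0)
  for (strand in c("+", "-")) {
    fidx <- which(frags$strand == strand)
    st <- sites[sites$strand == strand, , drop = FALSE]
    if (length(fidx) && nrow(st)) {
      P <- st$pos
      lo <- findInterval(frags$start[fidx] - 0.5, P) + 1L
      hi <- findInterval(frags$end[fidx] - 0.5, P)
      cnt <- pmax(hi - lo + 1L, 0L)
      pair_f <- rep(fidx, cnt)
      pair_s <- sequence(cnt) + rep(lo - 1L, cnt)
      if (length(pair_f)) {
        methylated <- runif(length(pair_f)) < st$beta[pair_s]
        damaged <- methylated & runif(length(pair_f)) < d_m5c
        n_meth <- n_meth + tabulate(pair_f[methylated], nbins = n)
        ev_frag <- c(ev_frag, pair_f[damaged])
        ev_pos <- c(ev_pos, P[pair_s[damaged]])
        ev_strand <- c(ev_strand, rep(strand, sum(damaged)))
      }
    }
  }
  # unmethylated template-strand Cs: plus template -> C count, minus -> G count
  nC_plus <- cum$C[frags$end + 1L] - cum$C[frags$start + 1L]
  nC_minus <- cum$G[frags$end + 1L] - cum$G[frags$start + 1L]
  n_template_C <- ifelse(frags$strand == "+", nC_plus, nC_minus)
  n_unmeth <- pmax(n_template_C - n_meth, 0L)
  n_u <- rbinom(n, n_unmeth, d_c)
  list(events = data.frame(frag = ev_frag, pos = ev_pos, strand = ev_strand,
                           stringsAsFactors = FALSE),
       n_u = n_u, dropped = n_u > 0L)
}

# build SAM-style read records for surviving fragments of one reference
.sim_reads_vec <- function(frags, events, carriers, seq_string, rname,
                           read_length, error_rate, base_quality,
                           low_quality_error_fraction = 0,
                           low_quality_phred = 20L, frag_offset = 0L) {
  n <- nrow(frags)
  rl <- as.integer(read_length)
  if (n == 0L) return(.empty_reads())
  plus <- frags$strand == "+"
  # per fragment: read A covers [start, start+rl), read B covers [end-rl, end)
  startA <- frags$start
  startB <- frags$end - rl
  # interleave reads: rows 2i-1 = read A, 2i = read B
  rstart <- as.integer(rbind(startA, startB))
  frag_of_read <- rep(seq_len(n), each = 2L)
  is_A <- rep(c(TRUE, FALSE), n)
  # read-of-pair and mapping strand: plus template => A=(R1,F), B=(R2,R);
  # minus template => A=(R2,F), B=(R1,R)
  plus_r <- rep(plus, each = 2L)
  is_r1 <- ifelse(plus_r, is_A, !is_A)
  reversed <- !is_A
  flag <- 1L + 2L + ifelse(reversed, 16L, 32L) + ifelse(is_r1, 64L, 128L)
  seq <- substring(seq_string, rstart + 1L, rstart + rl)
  len <- frags$end - frags$start
  tlen <- ifelse(is_A, rep(len, each = 2L), -rep(len, each = 2L))
  pnext <- as.integer(rbind(startB, startA)) + 1L
  qchar <- intToUtf8(base_quality + 33L)
  qual <- rep(strrep(qchar, rl), 2L * n)

  # apply molecule-level edits (variants first, then deamination damage),
  # then sequencing errors on top
  apply_edits <- function(seq, frag, pos, char) {
    # each (fragment, reference position) edit lands on every covering read
    for (readsel in list(2L * frag - 1L, 2L * frag)) {
      off <- pos - rstart[readsel] + 1L
      ok <- off >= 1L & off <= rl
      idx <- readsel[ok]; o <- off[ok]; ch <- char[ok]
      for (j in seq_along(idx)) substr(seq[idx[j]], o[j], o[j]) <- ch[j]
    }
    seq
  }
  if (nrow(carriers)) {
    seq <- apply_edits(seq, carriers$frag, carriers$pos, carriers$alt_base)
  }
  if (nrow(events)) {
    ch <- ifelse(events$strand == "+", "T", "A")
    seq <- apply_edits(seq, events$frag, events$pos, ch)
  }
  n_err <- rbinom(1L, 2L * n * rl, error_rate)
  errors <- data.frame(read = integer(), seqpos = integer(),
                       stringsAsFactors = FALSE)
  if (n_err > 0L) {
    eread <- sample.int(2L * n, n_err, replace = TRUE)
    epos <- sample.int(rl, n_err, replace = TRUE)
    lowq <- runif(n_err) < low_quality_error_fraction
    lowq_char <- intToUtf8(low_quality_phred + 33L)
    for (j in seq_len(n_err)) {
      cur <- substr(seq[eread[j]], epos[j], epos[j])
      substr(seq[eread[j]], epos[j], epos[j]) <-
        sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      if (lowq[j]) substr(qual[eread[j]], epos[j], epos[j]) <- lowq_char
    }
    errors <- data.frame(read = eread, seqpos = epos, lowq = lowq,
                         stringsAsFactors = FALSE)
  }
  list(reads = data.frame(
    qname = paste0(rname, ":frag", frag_offset + frag_of_read),
    flag = flag, rname = rname, pos = rstart + 1L, mapq = 60L,
    cigar = paste0(rl, "M"), rnext = "=", pnext = pnext, tlen = tlen,
    seq = seq, qual = qual, stringsAsFactors = FALSE
  ), errors = errors)
}

.empty_reads <- function() {
  list(reads = data.frame(qname = character(), flag = integer(),
                          rname = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          rnext = character(), pnext = integer(),
                          tlen = integer(), seq = character(),
                          qual = character(), stringsAsFactors = FALSE),
       errors = data.frame(read = integer(), seqpos = integer(),
                           stringsAsFactors = FALSE))
}

#' Simulate a RIMS-seq paired-end library
#'
#' End-to-end generator: fragments, per-molecule methylation and deamination,
#' blocking dropout, read-pair emission with sequencing errors, and a
#' machine-readable truth record.  The read table is an idealized coordinate
#' alignment (full-length matches, MAPQ 60, proper pairs) equivalent to the
#' SAM that [write_sam()] serializes.
#'
#' @param genome a [reference_set()] (one or more references).
#' @param methylome a [methylome_spec()], or a precomputed site table as
#'   returned by [annotate_methylated_sites()].
#' @param n_fragments fragments per reference (recycled), before dropout.
#'   Alternatively give `coverage`.
#' @param coverage target read coverage per reference; translated to
#'   `round(length * coverage / (2 * read_length))` fragments.
#' @param insert_mean,insert_sd insert-size distribution.
#' @param read_length read length (default 100).
#' @param model a [deamination_model()].
#' @param error_rate per-base sequencing error rate (default 5e-4).
#' @param base_quality constant Phred base quality (default 37, above the
#'   standard >= 35 filter).
#' @param n_variants,variant_allele_fraction germline C->T / G->A variants to
#'   inject (see [inject_variants()]).
#' @param allow_overlap permit overlapping mates (tests the counting
#'   orientation convention; default `FALSE`).
#' @param low_quality_error_fraction fraction of sequencing-error bases tagged
#'   with Phred 20 instead of `base_quality`, to exercise the quality filter.
#' @param seed RNG seed (all randomness flows from it).
#' @return object of class `"rims_sim"`: list with `genome`, `reads`
#'   (alignment table), and `truth` (sites, fragments, damage events, errors,
#'   variants, parameters).
#' @export
simulate_rims <- function(genome, methylome, n_fragments = NULL,
                          coverage = NULL, insert_mean = 300, insert_sd = 30,
                          read_length = 100L, model = deamination_model(),
                          error_rate = 5e-4, base_quality = 37L,
                          n_variants = 0L, variant_allele_fraction = 0.5,
                          allow_overlap = FALSE,
                          low_quality_error_fraction = 0, seed = NULL) {
  stopifnot(inherits(genome, "reference_set"))
  if (!is.null(seed)) set.seed(seed)
  sites <- if (inherits(methylome, "methylome_spec")) {
    annotate_methylated_sites(genome, methylome)
  } else methylome
  lens <- nchar(genome)
  if (is.null(n_fragments)) {
    if (is.null(coverage)) stop("give n_fragments or coverage")
    n_fragments <- round(lens * coverage / (2 * read_length))
  }
  n_fragments <- as.integer(rep_len(n_fragments, length(genome)))
  variants <- inject_variants(genome, n_variants, variant_allele_fraction,
                              exclude = sites)
  reads <- list(); errors <- list(); fragments <- list(); events <- list()
  carriers_all <- list()
  frag_offset <- 0L
  for (ri in seq_along(genome)) {
    rn <- names(genome)[ri]
    seq_string <- genome[[ri]]
    fr <- simulate_fragments(genome[ri], n_fragments[ri], insert_mean,
                             insert_sd, read_length, allow_overlap)
    dm <- .sim_damage_vec(fr, seq_string,
                          sites[sites$ref == rn, , drop = FALSE],
                          model$d_m5c, model$d_c)
    # molecule-level variant carriers
    va <- variants[variants$ref == rn, , drop = FALSE]
    carriers <- data.frame(frag = integer(), pos = integer(),
                           alt_base = character(), stringsAsFactors = FALSE)
    if (nrow(va) && nrow(fr)) {
      hit <- lapply(seq_len(nrow(va)), function(i) {
        ov <- which(fr$start <= va$pos[i] & fr$end > va$pos[i])
        ov <- ov[runif(length(ov)) < va$allele_fraction[i]]
        if (length(ov)) data.frame(frag = ov, pos = va$pos[i],
                                   alt_base = va$alt_base[i],
                                   stringsAsFactors = FALSE)
      })
      hit <- hit[!vapply(hit, is.null, logical(1L))]
      if (length(hit)) carriers <- do.call(rbind, hit)
    }
    keep <- !dm$dropped
    keep_idx <- which(keep)
    remap <- match(seq_len(nrow(fr)), keep_idx)  # old frag index -> kept index
    ev <- dm$events[keep[dm$events$frag], , drop = FALSE]
    ev$frag <- remap[ev$frag]
    ca <- carriers[keep[carriers$frag], , drop = FALSE]
    ca$frag <- remap[ca$frag]
    rr <- .sim_reads_vec(fr[keep_idx, , drop = FALSE], ev, ca, seq_string, rn,
                         read_length, error_rate, base_quality,
                         low_quality_error_fraction,
                         frag_offset = frag_offset)
    fr$dropped <- dm$dropped
    fr$n_u <- dm$n_u
    fr$id <- frag_offset + remap
    fragments[[rn]] <- fr
    if (nrow(ev)) {
      ev$ref <- rn
      ev$frag <- frag_offset + ev$frag
      ev$kind <- "m5C>T"
      events[[rn]] <- ev
    }
    if (nrow(ca)) {
      ca$ref <- rn
      ca$frag <- frag_offset + ca$frag
      carriers_all[[rn]] <- ca
    }
    reads[[rn]] <- rr$reads
    errors[[rn]] <- rr$errors
    frag_offset <- frag_offset + length(keep_idx)
  }
  reads <- do.call(rbind, reads)
  rownames(reads) <- NULL
  structure(list(
    genome = genome,
    reads = reads,
    truth = list(
      sites = sites,
      fragments = do.call(rbind, fragments),
      events = if (length(events)) do.call(rbind, events) else
        data.frame(frag = integer(), pos = integer(), strand = character(),
                   ref = character(), kind = character(),
                   stringsAsFactors = FALSE),
      errors = do.call(rbind, errors),
      variants = variants,
      carriers = if (length(carriers_all)) do.call(rbind, carriers_all) else NULL,
      params = list(insert_mean = insert_mean, insert_sd = insert_sd,
                    read_length = read_length, d_m5c = model$d_m5c,
                    d_c = model$d_c, error_rate = error_rate,
                    base_quality = base_quality,
                    allow_overlap = allow_overlap,
                    n_fragments = n_fragments),
      seed = seed
    )
  ), class = "rims_sim")
}

#' @export
print.rims_sim <- function(x, ...) {
  cat("RIMS-seq simulation:", length(x$genome), "reference(s),",
      nrow(x$reads), "reads,", nrow(x$truth$events), "deamination events\n")
  invisible(x)
}

#' Simulate a multi-member community library
#'
#' Fragments are allocated across members multinomially with probabilities
#' proportional to `weight * genome length`; each member carries its own
#' methylome.  Reads are pooled into a single alignment table over the
#' combined reference set.
#'
#' @param members list of members, each a list with `genome` (single-entry
#'   [reference_set()]), `methylome` ([methylome_spec()]) and `weight`
#'   (non-negative abundance weight).
#' @param total_fragments total fragments across members, before dropout.
#' @param ... further arguments passed to [simulate_rims()] (insert size,
#'   model, error rate, ...).
#' @param seed RNG seed.
#' @return a `"rims_sim"` object over the combined reference set, with
#'   `truth$allocation` recording the per-member fragment counts.
#' @export
simulate_community <- function(members, total_fragments, ..., seed = NULL) {
  stopifnot(length(members) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  w <- vapply(members, function(m) m$weight, numeric(1L))
  stopifnot(all(w >= 0), any(w > 0))
  lens <- vapply(members, function(m) nchar(m$genome[[1L]]), numeric(1L))
  p <- w * lens / sum(w * lens)
  alloc <- as.vector(stats::rmultinom(1L, total_fragments, p))
  genome <- reference_set(setNames(
    vapply(members, function(m) m$genome[[1L]], character(1L)),
    vapply(members, function(m) names(m$genome), character(1L))))
  sites <- do.call(rbind, lapply(seq_along(members), function(i) {
    annotate_methylated_sites(genome[i], members[[i]]$methylome)
  }))
  sim <- simulate_rims(genome, sites, n_fragments = alloc, ...)
  sim$truth$allocation <- data.frame(ref = names(genome), weight = w,
                                     fragments = alloc,
                                     stringsAsFactors = FALSE)
  sim
}
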