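# Independent oracles: deliberately brute-force, sharing no code with the
# implementation paths they check.

# IUPAC matching by full expansion of the pattern into concrete strings
oracle_iupac_matches <- function(pattern, text, offset) {
  expansion <- iupac_expand(pattern)
  substr(text, offset + 1, offset + nchar(pattern)) %in% expansion
}

# candidate-space size by explicit enumeration (feasible for k <= 5)
oracle_candidate_space <- function(k, b2, b3, bn) {
  deg <- c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 3, 3, 3, 3, 4)  # A..V, N last
  grid <- as.matrix(do.call(expand.grid, rep(list(1:15), k)))
  d <- matrix(deg[grid], nrow = nrow(grid))
  ok <- rowSums(d == 2) <= b2 & rowSums(d == 3) <= b3 & rowSums(d == 4) <= bn &
    grid[, 1L] != 15L & grid[, k] != 15L
  sum(ok)
}

# log10 one-sided Fisher (hypergeometric upper tail) by direct summation of
# log terms with log-sum-exp
oracle_log10_fisher <- function(fg_occ, fg_scan, bg_occ, bg_scan) {
  K <- fg_occ + bg_occ
  amax <- min(fg_scan, K)
  a <- fg_occ:amax
  logterm <- lchoose(fg_scan, a) + lchoose(bg_scan, K - a) -
    lchoose(fg_scan + bg_scan, K)
  m <- max(logterm)
  (m + log(sum(exp(logterm - m)))) / log(10)
}

# both-strand motif site scanner by sliding concrete expansion comparison
oracle_scan_sites <- function(genome_seq, motif, offset) {
  k <- nchar(motif)
  fwd <- iupac_expand(motif)
  revm <- iupac_expand(reverse_complement(motif))
  out <- list()
  for (s in 0:(nchar(genome_seq) - k)) {
    word <- substr(genome_seq, s + 1, s + k)
    if (word %in% fwd) {
      out[[length(out) + 1L]] <- data.frame(pos = s + offset - 1L,
                                            strand = "+")
    }
    if (word %in% revm) {
      out[[length(out) + 1L]] <- data.frame(pos = s + k - offset,
                                            strand = "-")
    }
  }
  if (!length(out)) return(data.frame(pos = integer(), strand = character()))
  unique(do.call(rbind, out))
}

# exhaustive motif search over the full canonical candidate space (toy sizes
# only): score every candidate with the package's counting + Fisher, return
# the global optimum under the same tie-breaking
oracle_exhaustive_best <- function(fg, bg, cfg) {
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  deg <- c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 3, 3, 3, 3, 4)
  best <- NULL
  for (k in cfg$min_motif_length:cfg$max_motif_length) {
    grid <- as.matrix(do.call(expand.grid, rep(list(1:15), k)))
    d <- matrix(deg[grid], nrow = nrow(grid))
    keep <- rowSums(d == 2) <= cfg$budget_2fold &
      rowSums(d == 3) <= cfg$budget_3fold &
      rowSums(d == 4) <= cfg$budget_n &
      grid[, 1L] != 15L & grid[, k] != 15L
    grid <- grid[keep, , drop = FALSE]
    for (r in seq_len(nrow(grid))) {
      idx <- grid[r, ]
      motif <- paste(codes[idx], collapse = "")
      cf <- count_occurrences(motif, fg)
      cb <- count_occurrences(motif, bg)
      lp <- score_motif(cf$occurrences, cf$scan_positions,
                        cb$occurrences, cb$scan_positions)
      cand <- list(motif = motif, lp = lp)
      if (is.null(best) || lp < best$lp ||
          (lp == best$lp && (nchar(motif) < nchar(best$motif) ||
            (nchar(motif) == nchar(best$motif) && motif < best$motif)))) {
        best <- cand
      }
    }
  }
  best
}
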