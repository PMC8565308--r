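# Shared small fixtures, built in code at test time.

# a modest simulated library with a Dcm-style methylome, reused across tests
small_ccwgg_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_genome(40000, 0.5, seed = 101, name = "chr")
      cache <<- list(
        genome = g,
        spec = methylome_spec("CCWGG", 2, 1),
        sim = simulate_rims(g, methylome_spec("CCWGG", 2, 1), coverage = 60,
                            model = deamination_model(0.01, 0.001),
                            error_rate = 0, seed = 102)
      )
    }
    cache
  }
})

# a noisier, deeper library where discovery has genuine power (used by the
# pipeline-level tests)
noisy_ccwgg_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_genome(100000, 0.5, seed = 103, name = "chr")
      cache <<- list(
        genome = g,
        sim = simulate_rims(g, methylome_spec("CCWGG", 2, 1), coverage = 150,
                            model = deamination_model(0.02, 0.001),
                            error_rate = 5e-4, seed = 104)
      )
    }
    cache
  }
})

# does any reported motif match a concrete target of the same length?
any_motif_covers <- function(motifs, target) {
  any(vapply(motifs, function(m) {
    nchar(m) == nchar(target) && iupac_matches(m, target, 0)
  }, logical(1)))
}

# hand-built single-read alignment table (all-M CIGAR) for filter tests
one_read_aln <- function(seq, pos = 1L, flag = 99L, qual = NULL, mapq = 60L,
                         rname = "chr", cigar = NULL) {
  rl <- nchar(seq)
  if (is.null(qual)) qual <- strrep("I", rl)   # Phred 40
  if (is.null(cigar)) cigar <- paste0(rl, "M")
  data.frame(qname = "r", flag = flag, rname = rname, pos = pos, mapq = mapq,
             cigar = cigar, rnext = "=", pnext = 1L, tlen = rl,
             seq = seq, qual = qual, stringsAsFactors = FALSE)
}

# windows with a planted centered motif vs uniform random background
planted_windows <- function(n, width, motif, at, seed, n_bg = n) {
  set.seed(seed)
  rand <- function(m) vapply(seq_len(m), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
  }, character(1))
  center <- (width + 1L) %/% 2L
  fg <- rand(n)
  substr(fg, center, center) <- "C"  # harvested windows always center on C
  for (i in seq_len(n)) substr(fg[i], at, at + nchar(motif) - 1L) <- motif
  bg <- rand(n_bg)
  substr(bg, center, center) <- "C"
  list(fg = fg, bg = bg)
}
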