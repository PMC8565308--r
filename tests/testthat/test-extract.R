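# a fixed 60-base reference for hand-built alignment fixtures, with a C at
# 1-based position 13 and a G at position 17
.tiny_genome <- function() {
  set.seed(987)
  b <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  b[13] <- "C"; b[17] <- "G"
  reference_set(c(chr = paste(b, collapse = "")))
}

test_that("ingest decodes flags and applies the read filters", {
  g <- .tiny_genome()
  seq10 <- substr(g[[1]], 11, 20)
  aln <- rbind(
    one_read_aln(seq10, pos = 11, flag = 99),    # accepted, (R1,F)
    one_read_aln(seq10, pos = 11, flag = 83),    # accepted, (R1,R)
    one_read_aln(seq10, pos = 11, flag = 163),   # accepted, (R2,F)
    one_read_aln(seq10, pos = 11, flag = 4),     # unmapped
    one_read_aln(seq10, pos = 11, flag = 99 + 8),    # mate unmapped
    one_read_aln(seq10, pos = 11, flag = 99 + 256),  # secondary
    one_read_aln(seq10, pos = 11, flag = 99 + 1024), # duplicate
    one_read_aln(seq10, pos = 11, flag = 99 + 2048), # supplementary
    one_read_aln(seq10, pos = 11, flag = 99, mapq = 5)  # low MAPQ
  )
  out <- ingest_alignments(aln, extraction_config())
  expect_equal(nrow(out), 3L)
  expect_equal(out$cell, c("R1F", "R1R", "R2F"))
  rep <- attr(out, "report")
  expect_equal(unname(rep["accepted"]), 3)
  expect_equal(unname(rep["dropped_mapq"]), 1)
  # neither/both read-of-pair flags -> warning and drop
  expect_warning(
    out2 <- ingest_alignments(one_read_aln(seq10, pos = 11, flag = 3L)),
    "read-of-pair")
  expect_equal(nrow(out2), 0L)
})

test_that("base quality and first-cycle filters gate counting but not depth", {
  g <- .tiny_genome()
  # reference position 13 (1-based) is C; plant a T there, read starts at 11
  seq10 <- substr(g[[1]], 11, 20)
  substr(seq10, 3, 3) <- "T"
  cfg <- extraction_config()

  sc <- accumulate_site_counts(one_read_aln(seq10, pos = 11, qual = strrep("I", 10)), g, cfg)
  expect_equal(unname(sc$refs$chr$counts[13, "R1F_T"]), 1L)  # Q40, cycle 3

  q <- strrep("I", 10); substr(q, 3, 3) <- "?"       # Phred 30 at the mismatch
  sc30 <- accumulate_site_counts(one_read_aln(seq10, pos = 11, qual = q), g, cfg)
  expect_equal(unname(sc30$refs$chr$counts[13, "R1F_T"]), 0L)
  expect_equal(unname(sc30$refs$chr$depth[13, "R1F"]), 1L)   # still contributes depth

  # same mismatch at the first cycle of a forward read -> ignored entirely
  seqc1 <- substr(g[[1]], 13, 22); substr(seqc1, 1, 1) <- "T"
  scc1 <- accumulate_site_counts(one_read_aln(seqc1, pos = 13), g, cfg)
  expect_equal(unname(scc1$refs$chr$counts[13, "R1F_T"]), 0L)
  expect_equal(unname(scc1$refs$chr$depth[13, "R1F"]), 0L)
  expect_equal(unname(scc1$refs$chr$depth[14, "R1F"]), 1L)

  # for a reverse-mapped read the first cycle is the LAST aligned base
  seqr <- substr(g[[1]], 4, 13); substr(seqr, 10, 10) <- "T"
  scr <- accumulate_site_counts(one_read_aln(seqr, pos = 4, flag = 83), g, cfg)
  expect_equal(unname(scr$refs$chr$counts[13, "R1R_T"]), 0L)
  expect_equal(unname(scr$refs$chr$depth[13, "R1R"]), 0L)
  scr2 <- accumulate_site_counts(
    one_read_aln(seqr, pos = 4, flag = 83), g,
    extraction_config(exclude_first_cycle = FALSE))
  expect_equal(unname(scr2$refs$chr$counts[13, "R1R_T"]), 1L)
})

test_that("CIGAR walking handles clips, insertions and deletions", {
  g <- .tiny_genome()
  cfg <- extraction_config()
  # 3S then 7M starting at ref 11: aligned bases are read positions 4..10
  seqs <- paste0("TTT", substr(g[[1]], 11, 17))
  sc <- accumulate_site_counts(
    one_read_aln(seqs, pos = 11, cigar = "3S7M"), g, cfg)
  expect_equal(sum(sc$refs$chr$depth), 7L)
  expect_equal(unname(sc$refs$chr$depth[11, "R1F"]), 1L)
  # 5M2D5M skips two reference bases
  seqd <- paste0(substr(g[[1]], 11, 15), substr(g[[1]], 18, 22))
  scd <- accumulate_site_counts(
    one_read_aln(seqd, pos = 11, cigar = "5M2D5M"), g, cfg)
  expect_equal(unname(scd$refs$chr$depth[16:17, "R1F"]), c(0L, 0L))
  expect_equal(unname(scd$refs$chr$depth[18, "R1F"]), 1L)
  # 5M2I5M consumes query without advancing the reference
  seqi <- paste0(substr(g[[1]], 11, 15), "AA", substr(g[[1]], 16, 20))
  sci <- accumulate_site_counts(
    one_read_aln(seqi, pos = 11, cigar = "5M2I5M"), g, cfg)
  expect_equal(sum(sci$refs$chr$depth), 9L)  # first cycle excluded
  expect_equal(unname(sci$refs$chr$depth[20, "R1F"]), 1L)
  # inconsistent CIGAR/SEQ errors out with the record identified
  expect_error(accumulate_site_counts(
    one_read_aln("ACGTA", pos = 11, cigar = "10M"), g, cfg), "CIGAR")
})

test_that("variant masking applies the >5% and >=5 reads rule jointly", {
  g <- .tiny_genome()  # position 13 is C
  mk <- function(n_alt, n_ref) {
    seq_alt <- substr(g[[1]], 11, 20); substr(seq_alt, 3, 3) <- "T"
    seq_ref <- substr(g[[1]], 11, 20)
    do.call(rbind, c(
      lapply(seq_len(n_alt), function(i) one_read_aln(seq_alt, pos = 11)),
      lapply(seq_len(n_ref), function(i) one_read_aln(seq_ref, pos = 11))))
  }
  cfg <- extraction_config()
  masked <- function(n_alt, n_ref) {
    sc <- accumulate_site_counts(mk(n_alt, n_ref), g, cfg)
    m <- compute_variant_mask(sc, g, cfg)
    12L %in% m$pos
  }
  expect_true(masked(6, 94))    # 6% of 100, 6 >= 5
  expect_false(masked(4, 76))   # 5% of 80 but only 4 reads
  expect_false(masked(8, 992))  # 8 reads but 0.8%
  # masked positions yield no events
  sc <- accumulate_site_counts(mk(6, 94), g, cfg)
  m <- compute_variant_mask(sc, g, cfg)
  ev <- call_event_positions(sc, g, m, cfg)
  expect_false(12L %in% ev$pos)
  ev_nomask <- call_event_positions(sc, g, NULL, cfg)
  expect_true(12L %in% ev_nomask$pos)
})

test_that("event classes map substitutions to strands and labels", {
  g <- .tiny_genome()
  cfg <- extraction_config()
  seq10 <- substr(g[[1]], 11, 20)
  mut <- function(s, at, b) { substr(s, at, at) <- b; s }
  # position 13 = C, position 17 = G (1-based)
  expect_equal(substr(g[[1]], 13, 13), "C")
  expect_equal(substr(g[[1]], 17, 17), "G")
  cases <- list(
    list(flag = 99L,  at = 3L, b = "T", strand = "+", label = "foreground"),
    list(flag = 163L, at = 7L, b = "A", strand = "-", label = "foreground"),
    list(flag = 99L,  at = 7L, b = "A", strand = "-", label = "background"),
    list(flag = 163L, at = 3L, b = "T", strand = "+", label = "background")
  )
  for (cs in cases) {
    aln <- one_read_aln(mut(seq10, cs$at, cs$b), pos = 11, flag = cs$flag)
    ev <- call_event_positions(accumulate_site_counts(aln, g, cfg), g, NULL, cfg)
    expect_equal(nrow(ev), 1L, info = cs$label)
    expect_equal(ev$pos, 10L + cs$at - 1L)
    expect_equal(ev$strand, cs$strand)
    expect_equal(ev$label, cs$label)
  }
  # the same mismatches on reverse-mapped reads are invisible under
  # forward_only but appear under all_strands
  aln_rev <- one_read_aln(mut(seq10, 3L, "T"), pos = 11, flag = 83L)
  sc_rev <- accumulate_site_counts(aln_rev, g, cfg)
  expect_equal(nrow(call_event_positions(sc_rev, g, NULL, cfg)), 0L)
  cfg_all <- extraction_config(count_orientation = "all_strands")
  sc_rev2 <- accumulate_site_counts(aln_rev, g, cfg_all)
  expect_equal(nrow(call_event_positions(sc_rev2, g, NULL, cfg_all)), 1L)
})

test_that("window harvest centers, strand-normalizes and drops bad windows", {
  g <- small_ccwgg_sim()$genome
  cfg <- extraction_config()
  ev <- data.frame(ref = "chr",
                   pos = c(200L, 300L, 5L),
                   strand = c("+", "-", "+"),
                   label = "foreground", support = 1L,
                   stringsAsFactors = FALSE)
  w <- harvest_windows(ev, g, cfg)
  expect_equal(nrow(w), 2L)  # the pos-5 window is end-truncated
  expect_equal(unname(attr(w, "report")["truncated"]), 1L)
  expect_equal(nchar(w$sequence[1]), 29L)
  expect_identical(w$sequence[1], substr(g[[1]], 187, 215))
  expect_identical(w$sequence[2],
                   reverse_complement(substr(g[[1]], 287, 315)))
  # minus windows center on C iff the reference base was G
  gsub <- substr(g[[1]], 301, 301)
  if (gsub == "G") expect_identical(substr(w$sequence[2], 15, 15), "C")
  # windows containing N are dropped
  gn <- reference_set(c(chr = paste0(strrep("A", 14), "C", strrep("N", 14))))
  wn <- harvest_windows(data.frame(ref = "chr", pos = 14L, strand = "+",
                                   label = "foreground", support = 1L),
                        gn, cfg)
  expect_equal(nrow(wn), 0L)
  expect_equal(unname(attr(wn, "report")["ambiguous"]), 1L)
})

test_that("events on simulated data with no damage or error are empty", {
  g <- generate_genome(20000, 0.5, seed = 71, name = "chr")
  sim <- simulate_rims(g, methylome_spec("CCWGG", 2, 1), coverage = 30,
                       model = deamination_model(0, 0), error_rate = 0,
                       seed = 72)
  res_ev <- call_event_positions(
    accumulate_site_counts(ingest_alignments(sim$reads), g), g, NULL)
  expect_equal(nrow(res_ev), 0L)
})
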