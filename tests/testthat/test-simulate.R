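test_that("generate_genome respects composition and preconditions", {
  g <- generate_genome(10000, 0.5, seed = 1)
  gc <- mean(strsplit(g[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 10000))  # ~99% binomial band
  g1 <- generate_genome(10, 1.0, seed = 2)
  expect_false(grepl("[AT]", g1[[1]]))
  expect_error(generate_genome(0, 0.5, seed = 3))
})

test_that("methylome offsets must index a C-admitting symbol", {
  expect_silent(methylome_spec("CCWGG", 2, 1))
  expect_silent(methylome_spec("RCGC", 2, 0.5))
  expect_error(methylome_spec("GATC", 2, 1), "admit C")
  expect_error(methylome_spec("CCWGG", 6, 1), "range")
})

test_that("site annotation matches the worked example and the scanner oracle", {
  g <- reference_set(c(chr = "GGCCAGGT"))
  sites <- annotate_methylated_sites(g, methylome_spec("CCWGG", 2, 1))
  expect_equal(sites$pos, c(3L, 5L))
  expect_equal(sites$strand, c("+", "-"))

  # non-palindromic: only the plus occurrence annotates
  g2 <- reference_set(c(chr = "ACCTGCAA"))
  s2 <- annotate_methylated_sites(g2, methylome_spec("ACCTGC", 2, 1))
  expect_equal(s2$pos, 1L)
  expect_equal(s2$strand, "+")

  # no occurrences -> empty
  s3 <- annotate_methylated_sites(g2, methylome_spec("CCWGG", 2, 1))
  expect_equal(nrow(s3), 0L)

  # random genomes against the brute-force both-strand scanner
  set.seed(5)
  for (i in 1:10) {
    gr <- generate_genome(600, 0.55, name = "r")
    for (m in list(c("CCWGG", 2), c("GCGC", 2), c("ACCTGC", 2))) {
      got <- annotate_methylated_sites(gr, methylome_spec(m[1], as.integer(m[2]), 1))
      want <- oracle_scan_sites(gr[[1]], m[1], as.integer(m[2]))
      expect_identical(paste(sort(paste(got$pos, got$strand))),
                       paste(sort(paste(want$pos, want$strand))),
                       info = m[1])
    }
  }
})

test_that("hemi-methylated (single-strand) specs annotate one strand only", {
  g <- generate_genome(5000, 0.5, seed = 9, name = "chr")
  both <- annotate_methylated_sites(g, methylome_spec("ACGC", 2, 1))
  plus <- annotate_methylated_sites(g, methylome_spec("ACGC", 2, 1, strand = "plus"))
  expect_true(all(plus$strand == "+"))
  expect_identical(plus$pos, both$pos[both$strand == "+"])
})

test_that("fragment simulation respects bounds and strand balance", {
  g <- generate_genome(5000, 0.5, seed = 21, name = "chr")
  fr <- simulate_fragments(g, 10000, insert_mean = 300, insert_sd = 30,
                           seed = 22)
  expect_true(all(fr$start >= 0L & fr$end <= 5000L))
  expect_true(all(fr$end - fr$start >= 200L))
  expect_lt(abs(mean(fr$strand == "+") - 0.5), 3 * sqrt(0.25 / 10000))
  expect_equal(nrow(simulate_fragments(g, 0)), 0L)
  tiny <- reference_set(c(chr = strrep("ACGT", 10)))
  expect_error(simulate_fragments(tiny, 1, read_length = 100), "shorter")
})

test_that("apply_deamination honors the damage model limits", {
  fx <- small_ccwgg_sim()
  sites <- annotate_methylated_sites(fx$genome, fx$spec)
  frag <- list(ref = "chr", start = 1000L, end = 1300L, strand = "+")

  # identity case
  d0 <- apply_deamination(frag, fx$genome, sites, deamination_model(0, 0), seed = 1)
  expect_identical(d0$template, substr(fx$genome[[1]], 1001, 1300))
  expect_false(d0$dropped)
  expect_equal(nrow(d0$events), 0L)

  # certain blocking
  d1 <- apply_deamination(frag, fx$genome, sites, deamination_model(0, 1), seed = 2)
  expect_true(d1$dropped)

  # certain conversion: every template-strand site becomes T
  d2 <- apply_deamination(frag, fx$genome, sites, deamination_model(1, 0), seed = 3)
  in_frag <- sites[sites$pos >= 1000 & sites$pos < 1300 & sites$strand == "+", ]
  expect_equal(sum(d2$events$kind == "m5C>T"), nrow(in_frag))
  expect_setequal(d2$events$pos[d2$events$kind == "m5C>T"], in_frag$pos)

  # minus-template fragments are damaged on the minus strand only
  fragm <- list(ref = "chr", start = 1000L, end = 1300L, strand = "-")
  d3 <- apply_deamination(fragm, fx$genome, sites, deamination_model(1, 0), seed = 4)
  in_fragm <- sites[sites$pos >= 1000 & sites$pos < 1300 & sites$strand == "-", ]
  expect_setequal(d3$events$pos[d3$events$kind == "m5C>T"], in_fragm$pos)
})

test_that("emit_read_pair realizes the R1/R2 orientation and echo geometry", {
  g <- small_ccwgg_sim()$genome
  sites <- annotate_methylated_sites(g, small_ccwgg_sim()$spec)

  # undamaged plus fragment: reads are exact substrings / revcomp
  frag <- apply_deamination(list(ref = "chr", start = 500L, end = 800L, strand = "+"),
                            g, sites, deamination_model(0, 0), seed = 1)
  pair <- emit_read_pair(frag, read_length = 100, error_rate = 0)
  expect_identical(pair$r1$read, substr(g[[1]], 501, 600))
  expect_identical(pair$r2$read, reverse_complement(substr(g[[1]], 701, 800)))
  expect_equal(pair$sam$flag, c(99L, 147L))
  expect_equal(pair$sam$pos, c(501L, 701L))
  expect_identical(pair$sam$seq[2], substr(g[[1]], 701, 800))

  # minus fragment: R2 maps forward at the start, R1 reverse at the end
  fragm <- apply_deamination(list(ref = "chr", start = 500L, end = 800L, strand = "-"),
                             g, sites, deamination_model(0, 0), seed = 2)
  pairm <- emit_read_pair(fragm, read_length = 100, error_rate = 0)
  expect_equal(pairm$sam$flag, c(163L, 83L))
  expect_identical(pairm$sam$seq[1], substr(g[[1]], 501, 600))
  expect_identical(pairm$r1$read,
                   reverse_complement(substr(g[[1]], 701, 800)))

  # dropped fragments are never sequenced
  dropped <- frag; dropped$dropped <- TRUE
  expect_null(emit_read_pair(dropped))
})

test_that("signature property: without sequencing error all mismatches fall in the signal classes", {
  fx <- small_ccwgg_sim()
  res <- rims_run(fx$sim, fx$genome)
  expect_gt(sum(res$events$label == "foreground"), 0)
  expect_equal(sum(res$events$label == "background"), 0)
  # spectrum: only C->T (R1) and G->A (R2) are non-zero
  sp <- res$spectrum
  hot <- (sp$read == "R1" & sp$ref_base == "C" & sp$alt_base == "T") |
         (sp$read == "R2" & sp$ref_base == "G" & sp$alt_base == "A")
  expect_true(all(sp$count[hot] > 0))
  expect_true(all(sp$count[!hot] == 0))
})

test_that("blocking dropout matches its expected survival rate", {
  g <- generate_genome(20000, 0.5, seed = 31, name = "chr")
  spec <- methylome_spec("CCWGG", 2, 1)
  sim <- simulate_rims(g, spec, n_fragments = 4000, model = deamination_model(0, 0.002),
                       error_rate = 0, seed = 32)
  fr <- sim$truth$fragments
  cum <- rimsseq:::.cum_base_counts(g[[1]], c("C", "G"))
  nC <- ifelse(fr$strand == "+", cum$C[fr$end + 1] - cum$C[fr$start + 1],
               cum$G[fr$end + 1] - cum$G[fr$start + 1])
  expected <- mean((1 - 0.002)^nC)
  observed <- mean(!fr$dropped)
  expect_lt(abs(observed - expected), 3 * sqrt(expected * (1 - expected) / 4000))
})

test_that("variant injection is molecule-level and dose-dependent", {
  g <- generate_genome(20000, 0.5, seed = 41, name = "chr")
  spec <- methylome_spec("CCWGG", 2, 1)
  expect_equal(nrow(inject_variants(g, 0)), 0L)
  sim <- simulate_rims(g, spec, coverage = 100, model = deamination_model(0, 0),
                       error_rate = 0, n_variants = 5,
                       variant_allele_fraction = 1, seed = 42)
  v <- sim$truth$variants
  sc <- accumulate_site_counts(ingest_alignments(sim$reads), g)
  counts <- sc$refs$chr$counts
  for (i in seq_len(nrow(v))) {
    alt_cols <- paste(rimsseq:::.CELLS, v$alt_base[i], sep = "_")
    ref_cols <- paste(rimsseq:::.CELLS, v$ref_base[i], sep = "_")
    alt <- sum(counts[v$pos[i] + 1, alt_cols])
    ref <- sum(counts[v$pos[i] + 1, ref_cols])
    expect_gt(alt, 0)
    expect_equal(ref, 0)  # allele fraction 1: every molecule carries the alt
  }
})

test_that("simulation is deterministic given a seed, and FASTQ/SAM round-trip", {
  g <- generate_genome(8000, 0.5, seed = 51, name = "chr")
  spec <- methylome_spec("GCGC", 2, 1)
  s1 <- simulate_rims(g, spec, coverage = 10, seed = 52)
  s2 <- simulate_rims(g, spec, coverage = 10, seed = 52)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$events, s2$truth$events)

  dir <- withr::local_tempdir()
  sam <- file.path(dir, "x.sam")
  write_sam(s1, sam)
  rt <- read_sam(sam)
  expect_equal(rt$references, setNames(8000L, "chr"))
  expect_equal(nrow(rt$reads), nrow(s1$reads))
  # same pileup whether counted from memory or from the SAM round-trip
  sc1 <- accumulate_site_counts(ingest_alignments(s1$reads), g)
  sc2 <- accumulate_site_counts(ingest_alignments(rt$reads), g)
  expect_identical(sc1$refs$chr$counts, sc2$refs$chr$counts)

  write_fastq(s1, file.path(dir, "x"))
  r1 <- readLines(file.path(dir, "x_R1.fastq"))
  expect_equal(length(r1) %% 4, 0)
  expect_equal(length(r1) / 4, sum(bitwAnd(s1$reads$flag, 64L) > 0))

  fa <- file.path(dir, "g.fasta")
  write_reference(g, fa)
  expect_identical(unclass(read_reference(fa))[["chr"]], g[["chr"]])
})

test_that("community simulation allocates fragments by weight and keeps methylomes separate", {
  m1 <- list(genome = generate_genome(20000, 0.5, seed = 61, name = "memberA"),
             methylome = methylome_spec("CCWGG", 2, 1), weight = 3)
  m2 <- list(genome = generate_genome(20000, 0.5, seed = 62, name = "memberB"),
             methylome = methylome_spec("GCGC", 2, 1), weight = 1)
  sim <- simulate_community(list(m1, m2), total_fragments = 4000,
                            model = deamination_model(0, 0), error_rate = 0,
                            seed = 63)
  alloc <- sim$truth$allocation
  expect_equal(sum(alloc$fragments), 4000)
  expect_lt(abs(alloc$fragments[1] - 3000), 3 * sqrt(4000 * 0.75 * 0.25))
  # sites only reflect each member's own methylome
  expect_true(all(sim$truth$sites$motif[sim$truth$sites$ref == "memberA"] == "CCWGG"))
  expect_true(all(sim$truth$sites$motif[sim$truth$sites$ref == "memberB"] == "GCGC"))
  # zero-weight member receives nothing
  m3 <- list(genome = generate_genome(5000, 0.5, seed = 64, name = "memberC"),
             methylome = methylome_spec("GATC", 4, 1), weight = 0)
  sim3 <- simulate_community(list(m1, m3), total_fragments = 500,
                             model = deamination_model(0, 0), seed = 65)
  expect_equal(sim3$truth$allocation$fragments[2], 0)
})
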