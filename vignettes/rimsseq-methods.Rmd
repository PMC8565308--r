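---
title: "Methylase specificity from deamination signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylase specificity from deamination signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement principle

RIMS-seq is a variant of standard Illumina DNA-seq for bacteria in which the
library, after adapter ligation, is subjected to a limited heat-alkaline
deamination step.  Two kinds of cytosine damage result, with opposite fates:

* **unmethylated C → U**: uracil blocks the high-fidelity polymerase used in
  library amplification, so the molecule silently drops out of the library;
* **m5C → T**: thymine is a perfectly ordinary base, so the molecule is
  amplified and sequenced, carrying a C→T change at the methylated position.

Because the damage sits on one specific strand of each sequenced molecule,
the resulting mismatches are asymmetric between the two reads of a pair:
C→T appears on read 1 (R1) and its reverse-complement echo, G→A, on read 2
(R2), both on forward-mapped reads in reference orientation.  The mirror
classes — G→A on R1, C→T on R2 — cannot be produced by this mechanism and
serve as a matched noise control.  Deamination is rare (a few per mille per
m5C for typical treatment times), so no single site is ever confidently
called; instead the *collective* sequence context of many rare events
identifies the methyltransferase recognition motif, at base resolution,
because only the methylated cytosine within the motif is ever hit.

The package implements the full computational side of this design:

1. `rims_sim` functions (`generate_genome()`, `methylome_spec()`,
   `simulate_rims()`, `simulate_community()`) generate paired-end libraries
   carrying the damage signature, with machine-readable ground truth;
2. `pileup_extract` functions (`ingest_alignments()`,
   `accumulate_site_counts()`, `compute_variant_mask()`,
   `call_event_positions()`, `harvest_windows()`) turn alignments into
   filtered, strand-stratified substitution counts and foreground/background
   context windows;
3. `motif_discovery` functions (`discover_all()` and friends) find IUPAC
   motifs over-represented in foreground windows;
4. `qc_stats` functions quantify the damage (substitution spectra, R1/R2
   imbalance folds, spike-in deamination-rate estimation, context tables,
   two-sample logos, community abundances).

## The generative model of the simulator

Each fragment is an independent molecule:

* start uniform over the reference; length Normal(`insert_mean`,
  `insert_sd`), rounded and truncated to `[2 * read_length, L]` (one read
  length when mate overlap is explicitly enabled); genomes are linear and
  fragments never wrap;
* a template strand (the strand read 1 reports in native orientation) is
  drawn Bernoulli(1/2);
* every annotated methylated site on the template strand is methylated on
  this molecule with probability β — molecule-level heterogeneity, which is
  how partial per-site methylation levels arise in bisulfite data;
* a methylated C converts to T with probability `d_m5c`; every unmethylated
  template-strand C converts to U with probability `d_c`; one or more U
  drops the molecule;
* read 1 is the first `read_length` bases of the damaged template, read 2
  the reverse complement of its last `read_length` bases; sequencing errors
  are uniform over the other three bases at `error_rate` per base, with
  constant Phred quality (37 by default, above the pipeline's ≥ 35 filter).

Only the template strand is ever damaged.  This is a phenomenological model,
chosen so that the operational foreground/background class definitions
recover the signal exactly: with non-overlapping mates (the default) all
damage mismatches land in (C→T, R1, forward) and (G→A, R2, forward), and the
background classes contain only sequencing error.  With overlapping mates
the complement-strand echo of each damage event also surfaces on the
reverse-mapped mate, which is precisely why the counting convention
(`count_orientation = "forward_only"`) ignores reverse-mapped reads; the
simulator's `allow_overlap` mode exists to exercise that convention.

Two deliberate simplifications, and what they mean for the tests: blocking
dropout is drawn per fragment as Binomial(#unmethylated template C, `d_c`)
rather than base-by-base (marginally identical; individual U positions are
never sequenced, so they are recorded only as a count), and damage events
are materialized only where they can be read.  The simulator emulates i.i.d.
genomes, uniform coverage, constant quality and idealized alignments; it
does not emulate mapping ambiguity, indels, PCR duplicates, quality decay
along cycles, GC bias, or oxidative (8-oxoG) damage.  Passing tests
therefore demonstrate the correctness of the statistical machinery under
the documented damage model, not robustness to every artifact of real
libraries.

## Extraction rules and their rationale

* **Base quality ≥ 35** for a base to be counted (it still contributes
  depth); **MAPQ ≥ 10**; unmapped, mate-unmapped, secondary, supplementary
  and duplicate records dropped.
* **First sequencing cycle ignored** — interpreted as the 5'-most raw base
  of every read (the *last* aligned base of a reverse-mapped read), since
  the excluded artifact is a cycle-1 chemistry artifact, not a property of
  reference coordinates.
* **True-variant mask**: a position is excluded when, pooling both
  read-of-pairs and strands, the C→T (at reference C) or G→A (at reference
  G) alternate count is ≥ 5 reads *and* > 5% of the filtered depth.  A true
  variant manifests in all four cells, so pooling maximizes power; genuine
  deamination stays far below 5% at practical depths.
* **Events are presence-based** (≥ 1 qualifying read) because deamination
  is rare; requiring two reads would erase the signal at normal coverage.
  One context window per event position (deduplicated across supporting
  reads).
* **Windows are 14 bp per side** (29-base windows) with minus-strand events
  reverse-complemented so the putatively deaminated C is always central;
  windows truncated by contig ends or containing N are dropped and counted.

## The discovery statistic and search

Foreground and background windows are compared per candidate motif by
sliding the motif over *every* offset of every window (overlaps counted) and
forming the 2×2 table of occurrences vs scan positions.  Significance is a
one-sided Fisher exact test (hypergeometric upper tail) computed in log
space via `phyper(log.p = TRUE)`, because real signals sit thousands of
orders of magnitude below double-precision underflow.  The reported
`log10_p_corrected` applies a Bonferroni factor equal to the closed-form
size of the candidate space: all IUPAC strings within the configured length
range (4–8) and degeneracy budgets (at most one 2-fold symbol, no 3-fold
symbols, up to four Ns by default), with N disallowed at either end — the
canonical form that prevents padded duplicates from inflating the space.
A motif is reported when the corrected p-value is below `p_threshold`
(1e-100 by default).  The threshold is configurable because genuinely
borderline motifs exist (an 8-bp site with a handful of genomic occurrences
can land around 1e-91); users chasing rare long motifs should lower it
consciously.

The search is deterministic and staged: exact k-mers occurring as
center-spanning substrings of foreground windows are scored exactly and the
best `seed_pool_size` retained (true motifs span the center because the
methylated C is central by construction); greedy hill-climbing then applies
the single best-improving edit — generalize one position to a degenerate
superset within budgets, or trim a terminal position — until the p-value
stops improving; the global best over everything evaluated is reported.
Ties break to lower p, then shorter motif, then lexicographic order.  An
exhaustive-enumeration oracle pins the search to the global optimum at toy
sizes in the test suite.  After each reported motif, every occurrence is
masked (replaced by N, which matches nothing — preserving window coordinates
for the offset histograms) in foreground and background alike, windows whose
center is masked are removed, and the search repeats until nothing reaches
the threshold ("mask and repeat").

The **methylated offset** is `1 +` the mode of the foreground
occurrence-start histogram relative to the window center, required to index
a C-admitting symbol (otherwise the result is flagged `offset_unresolved`).

Degenerate-superset reporting is a real behavior, not a defect: when a
near-cognate context is also methylated (star activity, e.g. ACGC beside
GCGC), the composite motif (RCGC) scores better than either component and is
what gets reported — matching how such activity is summarized in practice.
Conversely, on marginal data a minimal superset (e.g. GGSC for GGCC) can
edge out the exact motif by a fraction of an order of magnitude; tests that
care about identity therefore assert *coverage* of the true site, not string
equality, except at full study scale where the exact motif wins.

## The QC estimators

* **Spectrum/folds**: all 12 substitution classes per read-of-pair, rates as
  exact count ratios; the C→T R1/R2 fold tracks the achieved deamination
  level.
* **Spike-in rate estimate**: on a fully methylated control (an XP12-style
  phage where every C is m5C), `rate(C→T, R1, forward) − rate(C→T, R2,
  forward)`.  Subtracting the R2 rate cancels symmetric sequencing error, so
  no separate undamaged control is needed.  The CI is a Newcombe hybrid of
  the two Wilson intervals.
* **Two-sample logo**: per position in ±7 around the center, a two-sided
  two-proportion z-test (pooled SE, no continuity or multiplicity
  correction) on base frequencies, significant at α = 0.01.  Any monotone
  two-sample proportion test would do here; the z-test is used because the
  original logo tool's exact statistic is not part of this package's
  contract, and the choice is recorded in the output metadata.
* **Community abundance**: accepted primary alignments per reference over
  the total; extraction and discovery then run per reference — windows are
  never pooled across references.

## Reference study conditions

The acceptance-level tests and `scripts/acceptance.R` run simulated studies
whose conditions were fixed up front from the biology and from
expected-count arithmetic (the corrected 1e-100 threshold needs several
hundred motif-positive windows):

* *Dcm-like*: 1 Mb genome, GC 0.5, CCWGG fully methylated at the second C,
  120× coverage (2×100, insert 300 ± 30), `d_m5c` 0.01, `d_c` 0.001, error
  5e-4, plus a matched `d_m5c = 0` control.
* *Multi-motif*: same scale with GATC (offset 4) and CGCG (offset 1).
* *Non-palindromic pair*: ACCTGC/GCAGGT (offsets 2/2) are ~4× rarer than a
  5-mer, so the study uses a 2 Mb genome at 200× with `d_m5c` 0.025 — the
  strong-treatment end of the deamination range (0.5 M NaOH-style), which is
  what one would choose in the lab for rare sites.
* *Star activity*: GCGC on both strands plus hemi-methylated (plus-strand)
  ACGC, 0.5 Mb at 200×.
* *Partial methylation*: GGCC at β = 0.91 vs ACGT at β = 0.23 in one 0.6 Mb
  genome at 300×, `d_m5c` 0.02; detection thresholds are compared across a
  nested read-subsampling ladder.  The expected-count arithmetic matters
  here: at β = 0.23 the corrected significance only clears 1e-100 with a
  few-fold margin at this scale, which is the point — partially methylated
  motifs sit at the edge of detectability and need several-fold more reads.
* *Counting-orientation discriminator*: overlapping-mate libraries
  (insert 130 ± 10 at 2×100) with a dense motif (GCGC), 100×, `d_m5c` 0.0272
  (the strong end of the measured deamination range) and a 1e-4
  post-quality-filter error floor, so that the complement-strand echo
  dominates sequencing error in the reverse-mapped cells by an order of
  magnitude.
* *Spike-in estimator*: 20–30 kb fully methylated control at 200× across
  `d_m5c` ∈ {0.001, 0.003, 0.01}.
* *Community*: two 0.4 Mb members at 3:1 weights with distinct
  methylomes (CCWGG vs GCGC), `d_m5c` 0.025, ~300×/~100× member coverage.

Genome sizes are scaled-down stand-ins for multi-megabase bacterial
chromosomes, sized so that motif site counts (hundreds to thousands) and
per-site event probabilities match what the method needs in practice; the
same arithmetic says a 6-mer motif on a real 4.6 Mb genome at ~200× behaves
like the 2 Mb study here.

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open internally; SAM records and the
  reported methylated offset are 1-based.
* Reference N never matches any motif symbol and carries no counts; text N
  is also the masking symbol, and mask padding (rather than deletion)
  preserves window coordinates.
* Classes with zero depth report `NA` rates, not 0; a zero R2 rate makes the
  imbalance fold `Inf` with an explicit flag.
* Zero scan positions is an error in `score_motif()`; an empty foreground or
  a foreground below `min_foreground_windows` (50) is a warning and a normal
  "no motif" outcome.
* All randomness flows from a single seed; identical seeds and parameters
  give byte-identical reads, truth tables and artifacts.

## Known limitations

* Quantitative per-site methylation calling is out of scope by design: the
  deamination level is far too low for per-site estimates; the method
  characterizes the *specificity*, not site occupancy.
* m6A/m4C methylation produces no deamination signal and is invisible here.
* The Fisher statistic treats window positions as independent scan trials;
  overlapping occurrences and shared genomic context make this an
  approximation, which the Bonferroni correction and the extreme threshold
  absorb in practice.
* Very rare motifs (few genomic sites) need coverage and/or deamination
  level scaled accordingly, as in the lab.
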