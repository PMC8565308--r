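# Configuration objects shared across the pipeline.

#' Extraction configuration
#'
#' Filters and window geometry used when turning alignments into per-site
#' substitution counts and context windows.  Defaults mirror the standard
#' RIMS-seq analysis settings: base quality >= 35, mapping quality >= 10
#' (mpileup `-q 10`), the first sequencing cycle of every read ignored,
#' true-variant masking at > 5% alternate fraction with >= 5 supporting reads,
#' and 14 bp of flanking context on each side of an event.
#'
#' @param min_base_quality minimum Phred base quality for a base to be
#'   counted (default 35).  Bases below the threshold still contribute depth.
#' @param min_mapping_quality minimum MAPQ for a read to be used (default 10).
#' @param exclude_first_cycle drop the first sequencing cycle (the 5'-most raw
#'   base) of every read, a known chemistry artifact (default `TRUE`).
#' @param variant_mask_fraction alternate-allele fraction above which a
#'   position is treated as a true variant (default 0.05).
#' @param variant_mask_min_reads minimum alternate reads for masking
#'   (default 5).
#' @param window_flank bases of genomic context on each side of an event
#'   (default 14, i.e. 29-base windows).
#' @param count_orientation `"forward_only"` (default) restricts the
#'   substitution classes to forward-mapped reads of the stated read-of-pair;
#'   `"all_strands"` pools both mapping strands (sensitivity analysis).
#' @param read_filters drop unmapped, mate-unmapped, secondary, supplementary
#'   and duplicate-flagged records (default `TRUE`; the `-F 12 -F 256`
#'   convention plus duplicates/supplementaries).
#' @return a list of class `"rims_extraction_config"`.
#' @export
extraction_config <- function(min_base_quality = 35L,
                              min_mapping_quality = 10L,
                              exclude_first_cycle = TRUE,
                              variant_mask_fraction = 0.05,
                              variant_mask_min_reads = 5L,
                              window_flank = 14L,
                              count_orientation = c("forward_only", "all_strands"),
                              read_filters = TRUE) {
  count_orientation <- match.arg(count_orientation)
  cfg <- list(
    min_base_quality = as.integer(min_base_quality),
    min_mapping_quality = as.integer(min_mapping_quality),
    exclude_first_cycle = isTRUE(exclude_first_cycle),
    variant_mask_fraction = as.numeric(variant_mask_fraction),
    variant_mask_min_reads = as.integer(variant_mask_min_reads),
    window_flank = as.integer(window_flank),
    count_orientation = count_orientation,
    read_filters = isTRUE(read_filters)
  )
  stopifnot(cfg$min_base_quality >= 0L, cfg$min_mapping_quality >= 0L,
            cfg$variant_mask_fraction >= 0, cfg$variant_mask_min_reads >= 0L,
            cfg$window_flank >= 7L)
  structure(cfg, class = "rims_extraction_config")
}

#' Motif discovery configuration
#'
#' Controls the degenerate-motif search: motif length range, degeneracy
#' budgets (how many 2-fold, 3-fold and N symbols a candidate may contain),
#' the corrected p-value threshold, and search heuristics.  The default
#' budgets correspond to length-(4..8) motifs with at most one 2-fold symbol,
#' no 3-fold symbols and up to four Ns; the default significance threshold is
#' a Bonferroni-corrected p below 1e-100.
#'
#' @param max_motif_length,min_motif_length motif length range (defaults 8, 4).
#' @param budget_2fold,budget_3fold,budget_n degeneracy budgets (1, 0, 4).
#' @param p_threshold corrected p-value threshold (default 1e-100).
#' @param max_iterations maximum mask-and-repeat iterations (default 10).
#' @param seed_pool_size number of top-scoring exact seeds retained for
#'   hill-climbing (default 500).
#' @param min_foreground_windows minimum number of foreground windows for
#'   discovery to be attempted (default 50).
#' @return a list of class `"rims_discovery_config"`.
#' @export
discovery_config <- function(max_motif_length = 8L,
                             min_motif_length = 4L,
                             budget_2fold = 1L,
                             budget_3fold = 0L,
                             budget_n = 4L,
                             p_threshold = 1e-100,
                             max_iterations = 10L,
                             seed_pool_size = 500L,
                             min_foreground_windows = 50L) {
  cfg <- list(
    max_motif_length = as.integer(max_motif_length),
    min_motif_length = as.integer(min_motif_length),
    budget_2fold = as.integer(budget_2fold),
    budget_3fold = as.integer(budget_3fold),
    budget_n = as.integer(budget_n),
    p_threshold = as.numeric(p_threshold),
    max_iterations = as.integer(max_iterations),
    seed_pool_size = as.integer(seed_pool_size),
    min_foreground_windows = as.integer(min_foreground_windows)
  )
  stopifnot(cfg$min_motif_length <= cfg$max_motif_length,
            cfg$min_motif_length >= 1L,
            cfg$budget_2fold >= 0L, cfg$budget_3fold >= 0L, cfg$budget_n >= 0L,
            cfg$p_threshold > 0, cfg$p_threshold <= 1,
            cfg$max_iterations >= 1L, cfg$seed_pool_size >= 1L,
            cfg$min_foreground_windows >= 0L)
  structure(cfg, class = "rims_discovery_config")
}
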