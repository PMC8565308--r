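# Methylome specification and site annotation.

#' Specify a methylome as motif / offset / methylation-level triples
#'
#' Each entry describes one methyltransferase specificity: an IUPAC
#' recognition motif, the 1-based offset within the motif of the methylated
#' cytosine, and the per-molecule methylation probability beta (1 for the
#' fully methylated sites typical of restriction-modification systems).
#' `strand` restricts annotation to one strand for hemi-methylated
#' specificities (e.g. star activity at a non-palindromic near-cognate site).
#'
#' @param motif character vector of IUPAC motifs.
#' @param offset integer vector, 1-based methylated position within each motif;
#'   the motif symbol there must admit C.
#' @param beta numeric vector of per-molecule methylation probabilities.
#' @param strand `"both"` (default), `"plus"` or `"minus"`, recycled.
#' @return data.frame of class `"methylome_spec"`.
#' @examples
#' methylome_spec("CCWGG", 2, 1)  # Dcm-style, fully methylated
#' @export
methylome_spec <- function(motif, offset, beta = 1, strand = "both") {
  n <- length(motif)
  spec <- data.frame(
    motif = toupper(as.character(motif)),
    offset = as.integer(rep_len(offset, n)),
    beta = as.numeric(rep_len(beta, n)),
    strand = as.character(rep_len(strand, n)),
    stringsAsFactors = FALSE
  )
  stopifnot(all(spec$strand %in% c("both", "plus", "minus")),
            all(spec$beta >= 0), all(spec$beta <= 1))
  for (i in seq_len(n)) {
    m <- iupac_mask(spec$motif[i])
    k <- length(m)
    if (spec$offset[i] < 1L || spec$offset[i] > k) {
      stop("offset out of range for motif ", spec$motif[i])
    }
    if (bitwAnd(m[spec$offset[i]], 2L) == 0L) {
      stop("motif symbol at methylated offset must admit C: ",
           spec$motif[i], ":", spec$offset[i])
    }
  }
  class(spec) <- c("methylome_spec", "data.frame")
  spec
}

#' Annotate methylated cytosine sites defined by a methylome on a genome
#'
#' For a motif of length k with methylated offset o, every plus-strand
#' occurrence starting at s (0-based) yields a site (s + o - 1, +), and every
#' occurrence of the motif's reverse complement starting at s yields a site
#' (s + k - o, -).  Only positions whose strand base is actually C are kept
#' (a degenerate symbol at the methylated offset may also match non-C bases).
#' Duplicate (reference, position, strand) entries are merged keeping the
#' maximum beta.
#'
#' @param genome a [reference_set()].
#' @param spec a [methylome_spec()].
#' @return data.frame with columns `ref`, `pos` (0-based), `strand`, `motif`,
#'   `beta`.
#' @export
annotate_methylated_sites <- function(genome, spec) {
  stopifnot(inherits(spec, "methylome_spec"))
  out <- list()
  for (rn in names(genome)) {
    seq <- genome[[rn]]
    enc <- utf8ToInt(seq)
    for (i in seq_len(nrow(spec))) {
      motif <- spec$motif[i]
      k <- nchar(motif)
      o <- spec$offset[i]
      if (spec$strand[i] %in% c("both", "plus")) {
        s <- find_motif_hits(motif, seq)
        pos <- s + o - 1L
        pos <- pos[enc[pos + 1L] == 67L]  # strand base must be C
        if (length(pos)) {
          out[[length(out) + 1L]] <- data.frame(
            ref = rn, pos = pos, strand = "+", motif = motif,
            beta = spec$beta[i], stringsAsFactors = FALSE)
        }
      }
      if (spec$strand[i] %in% c("both", "minus")) {
        s <- find_motif_hits(reverse_complement(motif), seq)
        pos <- s + k - o
        pos <- pos[enc[pos + 1L] == 71L]  # plus-strand G = minus-strand C
        if (length(pos)) {
          out[[length(out) + 1L]] <- data.frame(
            ref = rn, pos = pos, strand = "-", motif = motif,
            beta = spec$beta[i], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ref = character(), pos = integer(), strand = character(),
                      motif = character(), beta = numeric(),
                      stringsAsFactors = FALSE))
  }
  sites <- do.call(rbind, out)
  # merge duplicates keeping max beta
  key <- paste(sites$ref, sites$pos, sites$strand)
  ord <- order(key, -sites$beta)
  sites <- sites[ord, , drop = FALSE]
  sites <- sites[!duplicated(key[ord]), , drop = FALSE]
  sites <- sites[order(sites$ref, sites$pos, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}
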