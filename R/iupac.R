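# IUPAC nucleotide algebra.
#
# Every symbol is represented internally as a 4-bit mask over {A, C, G, T}
# (A = 1, C = 2, G = 4, T = 8).  A pattern symbol matches a concrete text base
# iff the base's bit is set in the pattern mask.  Text bases are encoded with
# the same single-bit masks except that N encodes to 0, so an ambiguous
# reference base never matches any pattern symbol (including N): ambiguous
# positions must not create phantom motif hits.

IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L,
  N = 15L
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
  V = "B", H = "D", D = "H", B = "V",
  N = "N"
)

# bits set in 0:15 -> degeneracy of each mask value
MASK_POPCOUNT <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)

# lookup from char code (utf8) to pattern / text mask
.iupac_char_lut <- local({
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt(paste(names(IUPAC_MASK), collapse = ""))] <- unname(IUPAC_MASK)
  lut
})
.text_char_lut <- local({
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("ACGTN")] <- c(1L, 2L, 4L, 8L, 0L)
  lut
})

# inverse lookup: mask value -> IUPAC character
.MASK_TO_CHAR <- local({
  x <- rep(NA_character_, 16L)
  x[IUPAC_MASK + 1L] <- names(IUPAC_MASK)
  x
})

# strict superset symbols of each mask value (hill-climbing generalizations)
.SUPERSETS <- lapply(0:15, function(m) {
  cand <- unname(IUPAC_MASK)
  cand[bitwAnd(cand, m) == m & cand != m]
})

#' Encode an IUPAC pattern as a vector of base masks
#'
#' @param pattern single IUPAC string (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @return integer vector of 4-bit masks, one per symbol.
#' @keywords internal
iupac_mask <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, !is.na(pattern))
  codes <- utf8ToInt(toupper(pattern))
  if (any(codes > 127L)) stop("invalid IUPAC symbol in pattern: ", pattern)
  m <- .iupac_char_lut[codes]
  if (anyNA(m)) stop("invalid IUPAC symbol in pattern: ", pattern)
  m
}

#' Encode nucleotide text over {A,C,G,T,N} as base masks (N encodes to 0)
#' @keywords internal
text_mask <- function(text) {
  codes <- utf8ToInt(toupper(text))
  if (any(codes > 127L)) stop("invalid base in text")
  m <- .text_char_lut[codes]
  if (anyNA(m)) stop("text must be over {A,C,G,T,N}")
  m
}

#' Test whether an IUPAC pattern matches text at a given offset
#'
#' A pattern symbol matches a text base iff the base belongs to the symbol's
#' expansion set.  A text base `N` matches nothing, not even pattern `N`.
#'
#' @param pattern IUPAC string.
#' @param text concrete nucleotide string over \{A,C,G,T,N\}.
#' @param offset 0-based offset of the pattern within the text.
#' @return `TRUE` or `FALSE`.
#' @examples
#' iupac_matches("CCWGG", "TCCAGGA", 1)  # TRUE: CCAGG is a CCWGG instance
#' iupac_matches("NNNN", "ACGT", 0)      # TRUE
#' @export
iupac_matches <- function(pattern, text, offset) {
  pm <- iupac_mask(pattern)
  k <- length(pm)
  n <- nchar(text)
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 0L || offset + k > n) {
    stop("offset out of range: pattern of length ", k,
         " at offset ", offset, " in text of length ", n)
  }
  tm <- text_mask(substr(text, offset + 1L, offset + k))
  all(bitwAnd(pm, tm) > 0L)
}

#' Expand an IUPAC string into all matching concrete strings
#'
#' @param pattern IUPAC string.
#' @return character vector of concrete strings over \{A,C,G,T\}.
#' @export
iupac_expand <- function(pattern) {
  pm <- iupac_mask(pattern)
  bases <- c("A", "C", "G", "T")
  sets <- lapply(pm, function(m) bases[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L])
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

#' Reverse complement of an IUPAC string
#'
#' Symbol-wise complement (e.g. rc(R) = Y, rc(W) = W), reversed.  An
#' involution on the 15 non-gap IUPAC codes.
#'
#' @param s character vector of IUPAC strings.
#' @return character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("ACCTGC")  # "GCAGGT"
#' reverse_complement("CCWGG")   # "CCWGG" (IUPAC palindrome)
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s))
  up <- toupper(s)
  bad <- grepl(sprintf("[^%s]", paste(names(IUPAC_MASK), collapse = "")), up)
  if (any(bad)) stop("invalid IUPAC symbol in: ", up[bad][1L])
  comp <- chartr(paste(names(IUPAC_COMPLEMENT), collapse = ""),
                 paste(unname(IUPAC_COMPLEMENT), collapse = ""), up)
  vapply(comp, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Degeneracy class counts of an IUPAC string
#'
#' @param pattern IUPAC string.
#' @return integer vector `c(n2, n3, nN)`: number of 2-fold, 3-fold and N
#'   symbols.
#' @keywords internal
iupac_class_counts <- function(pattern) {
  d <- MASK_POPCOUNT[iupac_mask(pattern) + 1L]
  c(n2 = sum(d == 2L), n3 = sum(d == 3L), nN = sum(d == 4L))
}

#' Find all occurrences of an IUPAC pattern in a nucleotide text
#'
#' @param pattern IUPAC string.
#' @param text nucleotide string over \{A,C,G,T,N\}.
#' @return integer vector of 0-based start positions.
#' @export
find_motif_hits <- function(pattern, text) {
  pm <- iupac_mask(pattern)
  tm <- text_mask(text)
  k <- length(pm)
  n <- length(tm) - k + 1L
  if (n <= 0L) return(integer())
  ok <- bitwAnd(tm[seq_len(n)], pm[1L]) > 0L
  if (k > 1L) {
    for (j in 2L:k) {
      ok <- ok & bitwAnd(tm[j:(n + j - 1L)], pm[j]) > 0L
    }
  }
  which(ok) - 1L
}

#' Size of the canonical IUPAC candidate space
#'
#' Counts IUPAC strings of length `k` whose symbol-class multiset respects the
#' degeneracy budgets (at most `budget_2fold` two-fold symbols, `budget_3fold`
#' three-fold symbols and `budget_n` Ns) and whose first and last symbols are
#' not N (the canonical form, which prevents padded duplicates from inflating
#' the space).  Used as the Bonferroni correction factor for motif discovery.
#'
#' @param k motif length (scalar or vector).
#' @param budget_2fold,budget_3fold,budget_n degeneracy budgets.
#' @return numeric count (per element of `k`).
#' @examples
#' candidate_space_size(4, 0, 0, 0)  # 256
#' candidate_space_size(4, 1, 0, 0)  # 1792
#' @export
candidate_space_size <- function(k, budget_2fold = 1L, budget_3fold = 0L,
                                 budget_n = 4L) {
  vapply(as.integer(k), function(kk) {
    stopifnot(kk >= 1L)
    interior <- max(kk - 2L, 0L)
    total <- 0
    for (l in 0:min(budget_n, interior)) {
      rem <- kk - l
      for (i in 0:min(budget_2fold, rem)) {
        for (j in 0:min(budget_3fold, rem - i)) {
          total <- total + choose(interior, l) * choose(rem, i) *
            choose(rem - i, j) * 6^i * 4^j * 4^(rem - i - j)
        }
      }
    }
    total
  }, numeric(1L))
}

#' Multiple-testing correction factor for a discovery configuration
#'
#' Sum of [candidate_space_size()] over all motif lengths admitted by the
#' configuration.
#'
#' @param cfg a [discovery_config()].
#' @return numeric scalar, the Bonferroni factor.
#' @export
bonferroni_factor <- function(cfg) {
  sum(candidate_space_size(cfg$min_motif_length:cfg$max_motif_length,
                           cfg$budget_2fold, cfg$budget_3fold, cfg$budget_n))
}
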