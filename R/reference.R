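# Reference sequences.  A ReferenceSet is a named character vector of
# uppercase nucleotide strings over {A,C,G,T,N}.  All coordinates elsewhere in
# the package are 0-based, half-open intervals on the forward strand of these
# entries; the only 1-based coordinates are SAM records and the user-facing
# methylated offset within a reported motif.

#' Construct a reference set
#'
#' @param sequences named character vector of nucleotide sequences.
#' @return named uppercase character vector of class `"reference_set"`.
#' @export
reference_set <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("reference sequences must have unique, non-empty names")
  }
  sequences <- toupper(sequences)
  if (any(grepl("[^ACGTN]", sequences))) {
    stop("reference sequences must be over {A,C,G,T,N}")
  }
  structure(sequences, class = "reference_set")
}

#' @export
`[.reference_set` <- function(x, i) {
  structure(NextMethod(), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("ReferenceSet with", length(x), "sequence(s):\n")
  for (nm in names(x)) cat(sprintf("  %s  (%d bp)\n", nm, nchar(x[[nm]])))
  invisible(x)
}

#' Read a reference set from a FASTA file
#'
#' @param path FASTA file.
#' @return a [reference_set()].
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  reference_set(setNames(toupper(as.character(ss)), nm))
}

#' Write a reference set to FASTA (wrapped at 60 columns)
#'
#' @param ref a [reference_set()].
#' @param path output file.
#' @export
write_reference <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(unclass(ref))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Simulate a random genome
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#'
#' @param length genome length in bases (>= 1).
#' @param gc_fraction GC content in `[0, 1]` (default 0.5).
#' @param seed optional RNG seed; when `NULL` the current RNG state is used.
#' @param name reference name (default "sim").
#' @return a single-entry [reference_set()].
#' @export
generate_genome <- function(length, gc_fraction = 0.5, seed = NULL,
                            name = "sim") {
  length <- as.integer(length)
  stopifnot(length >= 1L, gc_fraction >= 0, gc_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  reference_set(setNames(paste(bases, collapse = ""), name))
}

# cumulative base counts, used for O(1) interval composition queries:
# cum[[b]][i + 1] = number of base b among positions [0, i)
.cum_base_counts <- function(seq_string, bases = c("C", "G")) {
  enc <- utf8ToInt(seq_string)
  out <- lapply(bases, function(b) cumsum(c(0L, enc == utf8ToInt(b))))
  names(out) <- bases
  out
}
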