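#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over the alphabet A/C/G/T/N (N is its own
#' complement).  Applying it twice returns the input.
#'
#' @param sequence Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("AAGG")  # "CCTT"
#' @export
reverse_complement <- function(sequence) {
  if (!is.character(sequence)) {
    stop("`sequence` must be a character vector", call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  out <- chartr("ACGT", "TGCA", sequence)
  vapply(strsplit(out, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Canonical form of a repeat motif
#'
#' The lexicographically smallest cyclic rotation of the motif, so that
#' phase-shifted reports of the same repeat (e.g. "TG" vs "GT") compare
#' equal.  The strand is deliberately not folded in: cluster members are
#' strand-normalised before motifs are compared.
#'
#' @param motif Character vector of motifs (length 1-6, alphabet A/C/G/T).
#' @return Character vector of canonical motifs.
#' @examples
#' canonical_motif(c("TG", "TAA"))  # "GT", "AAT"
#' @export
canonical_motif <- function(motif) {
  if (!is.character(motif)) stop("`motif` must be character", call. = FALSE)
  nc <- nchar(motif)
  if (any(is.na(motif)) || any(nc < 1L) || any(nc > 6L) ||
      any(grepl("[^ACGT]", motif))) {
    stop("motifs must be 1-6 characters over {A,C,G,T}", call. = FALSE)
  }
  vapply(motif, function(m) {
    k <- nchar(m)
    if (k == 1L) return(m)
    doubled <- paste0(m, m)
    min(vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L),
               character(1)))
  }, character(1), USE.NAMES = FALSE)
}

# TRUE when the motif is not a whole-number repetition of a shorter string
# ("ATAT" is not a valid dimer-of-dimers motif; only "AT" is reported).
is_primitive_motif <- function(motif) {
  vapply(motif, function(m) {
    k <- nchar(m)
    if (k == 1L) return(TRUE)
    divs <- seq_len(k - 1L)
    divs <- divs[k %% divs == 0L]
    !any(vapply(divs, function(d) {
      strrep(substr(m, 1L, d), k %/% d) == m
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}
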