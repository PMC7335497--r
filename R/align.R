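#' Global pairwise alignment with affine gaps
#'
#' Deterministic Needleman-Wunsch/Gotoh alignment used throughout the
#' pipeline: match +1, mismatch -1, gap open -4, gap extend -1 (a gap of
#' length L costs `gap_open + (L-1) * gap_extend`).  `N` never matches
#' anything.  Traceback ties are resolved preferring match/mismatch over a
#' gap in `b` over a gap in `a`, so results are reproducible across runs
#' and platforms.
#'
#' @param a,b Sequences (single strings over A/C/G/T/N).  In the
#'   centre-star multiple alignment `a` is the centre and `b` the member.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @param end_free When `TRUE`, end gaps in either sequence are free
#'   (overlap-style alignment, used for the clustering identity).
#' @return A list with `score`, gapped strings `a` and `b`, and `n_match`
#'   (aligned identical non-N base pairs).
#' @examples
#' align_pair("ACGTACGT", "ACGACGT")
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1,
                       gap_open = -4, gap_extend = -1, end_free = FALSE) {
  stopifnot(is.character(a), length(a) == 1L,
            is.character(b), length(b) == 1L)
  align_pair_cpp(a, b, match, mismatch, gap_open, gap_extend,
                 isTRUE(end_free))
}

#' Pairwise identity between two transcripts
#'
#' Identity is the number of identical aligned base pairs in an
#' end-gap-free global alignment divided by the length of the shorter
#' sequence.  When `params$compare_both_strands` the reverse complement of
#' `b` is tried as well and the better strand is returned (ties prefer
#' `+`).  `N` never counts as a match.
#'
#' @param a,b Sequences (single strings).
#' @param params A [cluster_params()] object.
#' @return A list with `identity` (fraction in \[0, 1\]) and `strand`
#'   (`"+"` or `"-"`, the orientation of `b` relative to `a`).
#' @examples
#' pairwise_identity("ACGTACGTAC", "GTACGTACGT")
#' @export
pairwise_identity <- function(a, b, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  shorter <- min(nchar(a), nchar(b))
  fwd <- align_pair(a, b, end_free = TRUE)
  id_fwd <- fwd$n_match / shorter
  if (!params$compare_both_strands) {
    return(list(identity = id_fwd, strand = "+"))
  }
  rev <- align_pair(a, reverse_complement(b), end_free = TRUE)
  id_rev <- rev$n_match / shorter
  if (id_rev > id_fwd) {
    list(identity = id_rev, strand = "-")
  } else {
    list(identity = id_fwd, strand = "+")
  }
}
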