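#' Repeat-mining thresholds
#'
#' Minimum number of repeat units per motif size for a tandem repeat to be
#' reported, plus the maximal interruption allowed inside a compound
#' microsatellite.  The defaults are the MISA settings used throughout the
#' pipeline: monomer-10, dimer-6, trimer-5, tetramer-5, pentamer-5,
#' hexamer-5, and a 100 bp compound interruption.
#'
#' @param min_repeats Integer vector of length 6; `min_repeats[k]` is the
#'   minimum repeat count for motifs of length `k`.  All values must be
#'   >= 2.
#' @param max_interruption Maximum number of interrupting bases (bp) between
#'   two repeat runs that still belong to one compound microsatellite.
#' @return A list of class `mining_thresholds`.
#' @examples
#' mining_thresholds()
#' mining_thresholds(min_repeats = c(12, 7, 5, 5, 5, 5))
#' @export
mining_thresholds <- function(min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L),
                              max_interruption = 100L) {
  min_repeats <- as.integer(min_repeats)
  if (length(min_repeats) != 6L || anyNA(min_repeats)) {
    stop("`min_repeats` must be six integers (unit sizes 1..6)", call. = FALSE)
  }
  if (any(min_repeats < 2L)) {
    stop("all repeat-count minimums must be >= 2", call. = FALSE)
  }
  max_interruption <- as.integer(max_interruption)
  if (is.na(max_interruption) || max_interruption < 0L) {
    stop("`max_interruption` must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(min_repeats = min_repeats, max_interruption = max_interruption),
    class = "mining_thresholds"
  )
}

#' Clustering parameters
#'
#' Controls the greedy cross-sample clustering of transcripts.  Identity is
#' defined as the number of identical aligned bases in an end-gap-free
#' global alignment divided by the length of the shorter sequence; both
#' strands of the incoming sequence are considered by default.
#'
#' @param identity_threshold Minimum identity (fraction) to join a cluster.
#'   Values below 0.80 are rejected: the shorter-length identity definition
#'   degrades below that point.
#' @param compare_both_strands Consider the reverse complement of each
#'   incoming sequence as well and keep the better-matching strand.
#' @param min_members Clusters with fewer members are dropped (polymorphism
#'   needs at least two homologs).
#' @param min_shared_kmers Prescreen: a candidate representative is aligned
#'   only when it shares at least this many distinct 11-mers (on either
#'   strand) with the incoming sequence.  Purely an optimisation; at the
#'   identities this pipeline accepts (>= 0.80) a true pair always shares
#'   far more.  Sequences shorter than 100 bp bypass the prescreen.
#' @return A list of class `cluster_params`.
#' @examples
#' cluster_params()
#' @export
cluster_params <- function(identity_threshold = 0.90,
                           compare_both_strands = TRUE,
                           min_members = 2L,
                           min_shared_kmers = 5L) {
  if (!is.numeric(identity_threshold) || length(identity_threshold) != 1L ||
      is.na(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1) {
    stop("`identity_threshold` must be a fraction in (0, 1]", call. = FALSE)
  }
  if (identity_threshold < 0.80) {
    stop("`identity_threshold` below 0.80 is not supported", call. = FALSE)
  }
  min_members <- as.integer(min_members)
  if (is.na(min_members) || min_members < 1L) {
    stop("`min_members` must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      identity_threshold = identity_threshold,
      compare_both_strands = isTRUE(compare_both_strands),
      min_members = min_members,
      min_shared_kmers = as.integer(min_shared_kmers)
    ),
    class = "cluster_params"
  )
}

#' Enrichment parameters
#'
#' Controls the filtering and polymorphism-calling stage: repeats closer
#' than `min_flank` bases to a sequence end are discarded (primers could
#' not be designed), mononucleotide runs are discarded, and homologous loci
#' are matched across cluster members by their flanking anchor sequence.
#'
#' @param min_flank Minimum flanking bases on each side of a repeat; loci
#'   with strictly fewer flanking bases are removed (a flank of exactly
#'   `min_flank` passes).
#' @param drop_mononucleotide Remove single-nucleotide repeat runs.
#' @param require_cross_file Only call a locus polymorphic when differing
#'   repeat counts occur in members from different input files; repeat
#'   differences among isoforms of one assembly are treated as artifacts.
#' @param flank_anchor_length Length (bp) of the flanking anchor compared
#'   between members when matching loci.
#' @param flank_max_mismatch Maximum mismatches tolerated in a flanking
#'   anchor; two loci match when either the upstream or the downstream
#'   anchors agree within this bound.
#' @param min_repeat_difference Minimum difference in repeat count between
#'   two members for a locus to be called polymorphic.
#' @param keep_compound Emit candidates lying inside compound
#'   microsatellites (flagged `inside_compound`) rather than suppressing
#'   them.
#' @return A list of class `enrichment_params`.
#' @examples
#' enrichment_params()
#' enrichment_params(min_flank = 80)
#' @export
enrichment_params <- function(min_flank = 50L,
                              drop_mononucleotide = TRUE,
                              require_cross_file = TRUE,
                              flank_anchor_length = 20L,
                              flank_max_mismatch = 4L,
                              min_repeat_difference = 1L,
                              keep_compound = TRUE) {
  min_flank <- as.integer(min_flank)
  flank_anchor_length <- as.integer(flank_anchor_length)
  flank_max_mismatch <- as.integer(flank_max_mismatch)
  min_repeat_difference <- as.integer(min_repeat_difference)
  if (is.na(min_flank) || min_flank < 0L) {
    stop("`min_flank` must be >= 0", call. = FALSE)
  }
  if (is.na(flank_anchor_length) || flank_anchor_length < 1L) {
    stop("`flank_anchor_length` must be >= 1", call. = FALSE)
  }
  if (is.na(flank_max_mismatch) ||
      flank_max_mismatch >= flank_anchor_length) {
    stop("`flank_max_mismatch` must be smaller than `flank_anchor_length`",
         call. = FALSE)
  }
  if (is.na(min_repeat_difference) || min_repeat_difference < 1L) {
    stop("`min_repeat_difference` must be >= 1", call. = FALSE)
  }
  structure(
    list(
      min_flank = min_flank,
      drop_mononucleotide = isTRUE(drop_mononucleotide),
      require_cross_file = isTRUE(require_cross_file),
      flank_anchor_length = flank_anchor_length,
      flank_max_mismatch = flank_max_mismatch,
      min_repeat_difference = min_repeat_difference,
      keep_compound = isTRUE(keep_compound)
    ),
    class = "enrichment_params"
  )
}
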