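# Perfect-repeat mining with MISA-style thresholds.
#
# A locus is a maximal run of whole copies of a primitive motif (unit size
# 1-6) meeting the per-unit-size minimum count.  "Maximal" means the run
# cannot be extended by one whole unit on either side; trailing partial
# copies are not counted.  N breaks a run and never occurs inside a motif.
# Runs whose motif reduces to a shorter period are reported only at the
# shortest period, and when two loci of different unit sizes cover exactly
# the same interval only the shorter-period one is kept.  Overlapping runs
# of the same unit size (possible for phase-shifted starts) are resolved in
# favour of the leftmost start.

find_ssrs_one <- function(sequence, thresholds) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  rows <- vector("list", 6L)
  for (k in 1:6) {
    min_rep <- thresholds$min_repeats[k]
    if (n < k * min_rep) next
    lhs <- chars[seq_len(n - k)]
    rhs <- chars[seq.int(k + 1L, n)]
    eq <- lhs == rhs & lhs != "N" & rhs != "N"
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- r$values & r$lengths >= k * (min_rep - 1L)
    if (!any(keep)) next
    a <- run_start[keep]
    len <- r$lengths[keep]
    copies <- len %/% k + 1L
    start <- a
    end <- a + copies * k - 1L
    motif <- substring(sequence, start, start + k - 1L)
    prim <- is_primitive_motif(motif)
    if (!any(prim)) next
    start <- start[prim]; end <- end[prim]
    motif <- motif[prim]; copies <- copies[prim]
    # leftmost precedence among overlapping same-unit-size runs
    keep_i <- rep(TRUE, length(start))
    last_end <- -1L
    for (i in seq_along(start)) {
      if (start[i] <= last_end) keep_i[i] <- FALSE else last_end <- end[i]
    }
    rows[[k]] <- data.frame(
      motif = motif[keep_i], unit_size = k,
      repeat_count = copies[keep_i],
      start = start[keep_i], end = end[keep_i]
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) return(NULL)
  # equal-interval loci across unit sizes: keep the shortest period
  out <- out[order(out$start, out$end, out$unit_size), , drop = FALSE]
  dup <- duplicated(out[, c("start", "end")])
  out <- out[!dup, , drop = FALSE]
  out[order(out$start, out$unit_size), , drop = FALSE]
}

#' Mine perfect microsatellites from transcripts
#'
#' Detects every maximal perfect 1-6 bp tandem repeat meeting the
#' per-unit-size repeat-count thresholds (defaults: monomer-10, dimer-6,
#' trimer-5, tetramer-5, pentamer-5, hexamer-5), then annotates compound
#' membership for runs separated by at most `max_interruption` bases (see
#' [merge_compound()]).
#'
#' @param transcripts Tibble from [read_transcripts()] /
#'   [read_transcript_set()].
#' @param thresholds A [mining_thresholds()] object.
#' @param annotate_compound Assign compound-group ids (default `TRUE`).
#' @return A tibble of repeat loci with columns `seq_id`, `source_tag`,
#'   `motif` (as it occurs on the reported strand), `canonical_motif`
#'   (smallest cyclic rotation), `unit_size`, `repeat_count`, `start`,
#'   `end` (1-based, inclusive) and `compound_group` (integer id shared by
#'   members of one compound microsatellite, `NA` otherwise), sorted by
#'   record and start.
#' @examples
#' tx <- tibble::tibble(seq_id = "t1", description = "", source_tag = "eco1",
#'                      sequence = strrep("AC", 8), length = 16L)
#' find_ssrs(tx)
#' @export
find_ssrs <- function(transcripts, thresholds = mining_thresholds(),
                      annotate_compound = TRUE) {
  stopifnot(is.data.frame(transcripts),
            inherits(thresholds, "mining_thresholds"))
  loci <- purrr::pmap(
    list(transcripts$seq_id, transcripts$source_tag, transcripts$sequence),
    function(id, tag, seq) {
      hits <- find_ssrs_one(seq, thresholds)
      if (is.null(hits)) return(NULL)
      tibble::tibble(
        seq_id = id, source_tag = tag,
        motif = hits$motif,
        canonical_motif = canonical_motif(hits$motif),
        unit_size = as.integer(hits$unit_size),
        repeat_count = as.integer(hits$repeat_count),
        start = as.integer(hits$start), end = as.integer(hits$end)
      )
    }
  )
  out <- dplyr::bind_rows(loci)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      seq_id = character(), source_tag = character(), motif = character(),
      canonical_motif = character(), unit_size = integer(),
      repeat_count = integer(), start = integer(), end = integer()
    )
  }
  out$compound_group <- NA_integer_
  if (annotate_compound && nrow(out) > 0L) {
    out <- merge_compound(out, thresholds)
  }
  out
}

#' Annotate compound microsatellites
#'
#' Consecutive repeat loci on one sequence whose gap (`next start - previous
#' end - 1`) is at most `max_interruption` bases share a `compound_group`
#' id; larger gaps, and loci without a close neighbour, leave it `NA`.  No
#' locus is merged away - compound membership is an annotation, so repeat
#' counts of component loci remain individually comparable downstream.
#'
#' @param loci Locus tibble from [find_ssrs()]; within each sequence the
#'   loci must be sorted by `start` (as `find_ssrs()` returns them).
#' @param thresholds A [mining_thresholds()] object (`max_interruption`).
#' @return The locus tibble with `compound_group` filled in; ids are unique
#'   across the whole table.
#' @export
merge_compound <- function(loci, thresholds = mining_thresholds()) {
  stopifnot(is.data.frame(loci), inherits(thresholds, "mining_thresholds"))
  if (nrow(loci) == 0L) {
    loci$compound_group <- integer(0)
    return(loci)
  }
  max_gap <- thresholds$max_interruption
  key <- paste(loci$source_tag, loci$seq_id, sep = "\r")
  split_idx <- split(seq_len(nrow(loci)), key)
  group <- rep(NA_integer_, nrow(loci))
  next_id <- 1L
  for (idx in split_idx) {
    st <- loci$start[idx]
    if (is.unsorted(st)) {
      stop("loci must be sorted by start within each sequence",
           call. = FALSE)
    }
    if (length(idx) < 2L) next
    gap <- st[-1L] - loci$end[idx][-length(idx)] - 1L
    linked <- gap <= max_gap
    # runs of linked neighbours form one compound group
    grp_local <- cumsum(c(TRUE, !linked))
    for (g in unique(grp_local)) {
      members <- idx[grp_local == g]
      if (length(members) >= 2L) {
        group[members] <- next_id
        next_id <- next_id + 1L
      }
    }
  }
  loci$compound_group <- group
  loci
}

#' Write a MISA-style repeat report
#'
#' One row per locus: sequence id, per-sequence locus number, SSR type
#' (`p1`..`p6`, or `c` for members of a compound group), the repeat in
#' `(motif)count` notation, its size in bp and its 1-based inclusive
#' coordinates.  Tab-separated.
#'
#' @param loci Locus tibble from [find_ssrs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_misa_report <- function(loci, path) {
  stopifnot(is.data.frame(loci))
  tab <- loci |>
    dplyr::group_by(.data$source_tag, .data$seq_id) |>
    dplyr::mutate(ssr_nr = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      ID = .data$seq_id,
      `SSR nr.` = .data$ssr_nr,
      `SSR type` = ifelse(is.na(.data$compound_group), paste0("p", .data$unit_size), "c"),
      SSR = paste0("(", .data$motif, ")", .data$repeat_count),
      size = .data$end - .data$start + 1L,
      start = .data$start,
      end = .data$end
    )
  readr::write_tsv(tab, path)
  invisible(path)
}
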