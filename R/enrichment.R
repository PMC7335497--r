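# Polymorphic-candidate enrichment.  Pipeline order within a cluster:
# flank/mononucleotide filtering -> paralogy false-positive screen ->
# cross-member locus matching by flanking anchors -> repeat-count
# comparison.  Every locus, group or cluster that is discarded carries an
# explicit reason so decoy rejection can be audited.

#' Filter repeat loci before polymorphism calling
#'
#' Removes mononucleotide runs (when `drop_mononucleotide`) and loci lying
#' closer than `min_flank` bases to either sequence end - a flank of
#' exactly `min_flank` passes, strictly fewer fails.  Order is preserved.
#'
#' @param loci Locus tibble (any number of sequences; lengths are joined
#'   from `transcripts`).
#' @param transcripts Transcript tibble providing sequence lengths.
#' @param params An [enrichment_params()] object.
#' @return A list with `kept` (filtered locus tibble, plus `left_flank` and
#'   `right_flank` columns) and `dropped` (removed loci with a `reason`
#'   column: `"mononucleotide"` or `"flank"`).
#' @export
filter_loci <- function(loci, transcripts, params = enrichment_params()) {
  stopifnot(is.data.frame(loci), is.data.frame(transcripts),
            inherits(params, "enrichment_params"))
  lens <- transcripts |>
    dplyr::select("source_tag", "seq_id", seq_length = "length")
  loci <- dplyr::left_join(loci, lens, by = c("source_tag", "seq_id"))
  if (anyNA(loci$seq_length)) {
    stop("loci reference sequences absent from the transcript table",
         call. = FALSE)
  }
  loci$left_flank <- loci$start - 1L
  loci$right_flank <- loci$seq_length - loci$end
  loci$seq_length <- NULL
  reason <- rep(NA_character_, nrow(loci))
  if (params$drop_mononucleotide) {
    reason[loci$unit_size == 1L] <- "mononucleotide"
  }
  flank_fail <- is.na(reason) &
    (loci$left_flank < params$min_flank | loci$right_flank < params$min_flank)
  reason[flank_fail] <- "flank"
  list(
    kept = loci[is.na(reason), , drop = FALSE],
    dropped = dplyr::mutate(loci[!is.na(reason), , drop = FALSE],
                            reason = reason[!is.na(reason)])
  )
}

#' Screen a cluster for paralogy-driven false positives
#'
#' A cluster is discarded when, for any motif, one member carries two or
#' more repeat loci of that motif while another member carries strictly
#' fewer: a same-motif copy present in some members but missing from
#' others is the signature of paralogous cluster members (or a chimeric
#' assembly), not of repeat-count polymorphism.  Motifs are compared in
#' canonical form together with their unit size.
#'
#' @param cluster_members Tibble of the cluster's members (`source_tag`,
#'   `seq_id`).
#' @param loci Filtered locus tibble for those members.
#' @return A list: `keep` (logical) and, when dropped, `reason`, `motif`,
#'   `member_high`, `member_low`.
#' @export
screen_false_positive <- function(cluster_members, loci) {
  stopifnot(is.data.frame(cluster_members), is.data.frame(loci))
  member_keys <- paste(cluster_members$source_tag, cluster_members$seq_id,
                       sep = "|")
  if (nrow(loci) > 0L) {
    motifs <- unique(loci[, c("canonical_motif", "unit_size")])
    for (r in seq_len(nrow(motifs))) {
      sel <- loci$canonical_motif == motifs$canonical_motif[r] &
        loci$unit_size == motifs$unit_size[r]
      locus_keys <- paste(loci$source_tag[sel], loci$seq_id[sel], sep = "|")
      counts <- vapply(member_keys,
                       function(k) sum(locus_keys == k), integer(1))
      if (max(counts) >= 2L && min(counts) < max(counts)) {
        return(list(
          keep = FALSE,
          reason = "false_positive:same-motif count mismatch",
          motif = motifs$canonical_motif[r],
          member_high = member_keys[which.max(counts)],
          member_low = member_keys[which.min(counts)]
        ))
      }
    }
  }
  list(keep = TRUE)
}

anchor_mismatches <- function(up_a, up_b, down_a, down_b) {
  min(hamming_cpp(up_a, up_b), hamming_cpp(down_a, down_b))
}

#' Match homologous repeat loci across cluster members
#'
#' Within one strand-normalised cluster, loci from different members are
#' grouped as the "same" locus when their canonical motif and unit size
#' match and their flanking anchors agree: the `flank_anchor_length` bases
#' immediately upstream of both loci, or the bases immediately downstream,
#' differ at no more than `flank_max_mismatch` positions.  Pairing is
#' greedy on best anchor agreement (fewest mismatches; ties by leftmost
#' position), each locus joins at most one group, and a group holds at
#' most one locus per member.  Groups with fewer than two members are
#' discarded.
#'
#' @param cluster_members Cluster member tibble (must be strand-normalised:
#'   any `-` strand is an error).
#' @param loci Filtered locus tibble for the cluster's members.
#' @param transcripts Normalised transcript tibble (for flank extraction).
#' @param params An [enrichment_params()] object.
#' @return A tibble of grouped loci: the locus columns plus `group_id`.
#' @export
match_loci <- function(cluster_members, loci, transcripts,
                       params = enrichment_params()) {
  stopifnot(is.data.frame(cluster_members), is.data.frame(loci),
            is.data.frame(transcripts),
            inherits(params, "enrichment_params"))
  if ("strand" %in% names(cluster_members) &&
      any(cluster_members$strand == "-")) {
    stop("cluster must be strand-normalised before locus matching",
         call. = FALSE)
  }
  empty <- dplyr::mutate(loci[0, , drop = FALSE], group_id = integer(0))
  if (nrow(loci) < 2L) return(empty)

  key <- function(tag, id) paste(tag, id, sep = "\r")
  tx_key <- key(transcripts$source_tag, transcripts$seq_id)
  row_tx <- match(key(loci$source_tag, loci$seq_id), tx_key)
  if (anyNA(row_tx)) {
    stop("loci reference sequences absent from the transcript table",
         call. = FALSE)
  }
  al <- params$flank_anchor_length
  up <- substr(transcripts$sequence[row_tx],
               pmax(1L, loci$start - al), loci$start - 1L)
  down <- substr(transcripts$sequence[row_tx], loci$end + 1L,
                 pmin(nchar(transcripts$sequence[row_tx]), loci$end + al))
  member <- key(loci$source_tag, loci$seq_id)

  # candidate pairs: same canonical motif + unit size, different members,
  # anchors within tolerance
  pairs <- NULL
  idx <- seq_len(nrow(loci))
  combos <- utils::combn(idx, 2L)
  mm <- integer(ncol(combos))
  ok <- logical(ncol(combos))
  for (c_i in seq_len(ncol(combos))) {
    i <- combos[1L, c_i]; j <- combos[2L, c_i]
    if (member[i] == member[j]) next
    if (loci$canonical_motif[i] != loci$canonical_motif[j] ||
        loci$unit_size[i] != loci$unit_size[j]) next
    d <- anchor_mismatches(up[i], up[j], down[i], down[j])
    if (d <= params$flank_max_mismatch) {
      ok[c_i] <- TRUE
      mm[c_i] <- d
    }
  }
  if (!any(ok)) return(empty)
  pi <- combos[1L, ok]; pj <- combos[2L, ok]; pmm <- mm[ok]
  o <- order(pmm, pmin(loci$start[pi], loci$start[pj]),
             pmax(loci$start[pi], loci$start[pj]), pi, pj)
  pi <- pi[o]; pj <- pj[o]

  group_of <- rep(NA_integer_, nrow(loci))
  group_members <- list() # group id -> member keys present
  next_group <- 0L
  for (p in seq_along(pi)) {
    i <- pi[p]; j <- pj[p]
    gi <- group_of[i]; gj <- group_of[j]
    if (is.na(gi) && is.na(gj)) {
      next_group <- next_group + 1L
      group_of[c(i, j)] <- next_group
      group_members[[next_group]] <- c(member[i], member[j])
    } else if (is.na(gj) && !is.na(gi)) {
      if (!(member[j] %in% group_members[[gi]])) {
        group_of[j] <- gi
        group_members[[gi]] <- c(group_members[[gi]], member[j])
      }
    } else if (is.na(gi) && !is.na(gj)) {
      if (!(member[i] %in% group_members[[gj]])) {
        group_of[i] <- gj
        group_members[[gj]] <- c(group_members[[gj]], member[i])
      }
    } # both grouped: leave as is
  }
  out <- loci[!is.na(group_of), , drop = FALSE]
  out$group_id <- group_of[!is.na(group_of)]
  sizes <- table(out$group_id)
  out <- out[out$group_id %in% as.integer(names(sizes)[sizes >= 2L]), ,
             drop = FALSE]
  out[order(out$group_id, out$source_tag, out$seq_id), , drop = FALSE]
}

#' Call repeat-count polymorphism within a locus group
#'
#' A locus group is polymorphic when its maximum and minimum repeat counts
#' differ by at least `min_repeat_difference` and, when
#' `require_cross_file`, the differing counts occur in members from
#' different input files.
#'
#' @param group One locus group (rows of the [match_loci()] output sharing
#'   a `group_id`).
#' @param params An [enrichment_params()] object.
#' @return A list: `polymorphic` (logical), `reason` (when not),
#'   `max_repeat_difference`, `inside_compound`.
#' @export
detect_polymorphic <- function(group, params = enrichment_params()) {
  stopifnot(is.data.frame(group), inherits(params, "enrichment_params"))
  counts <- group$repeat_count
  diff_all <- max(counts) - min(counts)
  inside_compound <- any(!is.na(group$compound_group))
  if (diff_all < params$min_repeat_difference) {
    return(list(polymorphic = FALSE, reason = "no_repeat_difference",
                max_repeat_difference = diff_all,
                inside_compound = inside_compound))
  }
  if (params$require_cross_file) {
    cross_diff <- 0L
    tags <- group$source_tag
    for (i in seq_along(counts)) {
      for (j in seq_along(counts)) {
        if (tags[i] != tags[j]) {
          cross_diff <- max(cross_diff, abs(counts[i] - counts[j]))
        }
      }
    }
    if (cross_diff < params$min_repeat_difference) {
      return(list(polymorphic = FALSE, reason = "within_file_only",
                  max_repeat_difference = diff_all,
                  inside_compound = inside_compound))
    }
  }
  list(polymorphic = TRUE, reason = NA_character_,
       max_repeat_difference = diff_all, inside_compound = inside_compound)
}

#' Enrich polymorphic repeat candidates across clusters
#'
#' Runs the full enrichment stage over strand-normalised clusters:
#' [filter_loci()], then [screen_false_positive()] per cluster, then
#' [match_loci()] and [detect_polymorphic()].  Every discarded locus,
#' cluster and group is logged with its reason.
#'
#' @param clusters Strand-normalised cluster tibble.
#' @param transcripts Strand-normalised transcript tibble.
#' @param loci Strand-normalised locus tibble.
#' @param params An [enrichment_params()] object.
#' @return A list with:
#'   * `candidates`: one row per member locus of each polymorphic
#'     candidate (`candidate_id`, `cluster_id`, `canonical_motif`,
#'     `unit_size`, `source_tag`, `seq_id`, `motif`, `repeat_count`,
#'     `start`, `end`, `left_flank`, `right_flank`, `inside_compound`,
#'     `max_repeat_difference`), sorted by cluster and leftmost position;
#'   * `dropped_loci`: filtered-out loci with reasons;
#'   * `dropped_clusters`: clusters removed by the false-positive screen;
#'   * `dropped_groups`: matched groups not called polymorphic, with
#'     reasons (`no_repeat_difference`, `within_file_only`,
#'     `inside_compound` when compound candidates are suppressed);
#'   * `n_groups`: number of matched locus groups.
#' @export
enrich_candidates <- function(clusters, transcripts, loci,
                              params = enrichment_params()) {
  stopifnot(is.data.frame(clusters), is.data.frame(transcripts),
            is.data.frame(loci), inherits(params, "enrichment_params"))
  filt <- filter_loci(loci, transcripts, params)
  kept <- filt$kept

  candidates <- list()
  dropped_clusters <- list()
  dropped_groups <- list()
  n_groups <- 0L
  cand_id <- 0L

  for (cid in unique(clusters$cluster_id)) {
    members <- clusters[clusters$cluster_id == cid, , drop = FALSE]
    member_key <- paste(members$source_tag, members$seq_id, sep = "\r")
    cl_loci <- kept[paste(kept$source_tag, kept$seq_id, sep = "\r") %in%
                      member_key, , drop = FALSE]
    fp <- screen_false_positive(members, cl_loci)
    if (!fp$keep) {
      dropped_clusters[[length(dropped_clusters) + 1L]] <- tibble::tibble(
        cluster_id = cid, reason = fp$reason, motif = fp$motif,
        member_high = fp$member_high, member_low = fp$member_low
      )
      next
    }
    groups <- match_loci(members, cl_loci, transcripts, params)
    if (nrow(groups) == 0L) next
    for (g in unique(groups$group_id)) {
      grp <- groups[groups$group_id == g, , drop = FALSE]
      n_groups <- n_groups + 1L
      call <- detect_polymorphic(grp, params)
      suppress_compound <- call$polymorphic && call$inside_compound &&
        !params$keep_compound
      if (call$polymorphic && !suppress_compound) {
        cand_id <- cand_id + 1L
        candidates[[cand_id]] <- dplyr::mutate(
          dplyr::select(grp, -"group_id"),
          candidate_id = cand_id,
          cluster_id = cid,
          inside_compound = call$inside_compound,
          max_repeat_difference = call$max_repeat_difference
        )
      } else {
        dropped_groups[[length(dropped_groups) + 1L]] <- tibble::tibble(
          cluster_id = cid,
          canonical_motif = grp$canonical_motif[1L],
          reason = if (suppress_compound) "inside_compound" else call$reason,
          members = paste(paste(grp$source_tag, grp$seq_id, sep = "|"),
                          collapse = ","),
          repeat_counts = paste(grp$repeat_count, collapse = ",")
        )
      }
    }
  }

  cand <- dplyr::bind_rows(candidates)
  if (nrow(cand) == 0L) {
    cand <- tibble::tibble(
      candidate_id = integer(), cluster_id = integer(),
      canonical_motif = character(), unit_size = integer(),
      source_tag = character(), seq_id = character(), motif = character(),
      repeat_count = integer(), start = integer(), end = integer(),
      left_flank = integer(), right_flank = integer(),
      compound_group = integer(), inside_compound = logical(),
      max_repeat_difference = integer()
    )
  } else {
    leftmost <- cand |>
      dplyr::group_by(.data$candidate_id) |>
      dplyr::summarise(leftmost = min(.data$start), .groups = "drop")
    ord <- leftmost[order(leftmost$candidate_id), ]
    cand <- dplyr::left_join(cand, ord, by = "candidate_id") |>
      dplyr::arrange(.data$cluster_id, .data$leftmost, .data$candidate_id,
                     .data$source_tag, .data$seq_id) |>
      dplyr::select(-"leftmost")
    # renumber candidates in report order
    cand$candidate_id <- match(cand$candidate_id, unique(cand$candidate_id))
    cand <- dplyr::relocate(cand, "candidate_id", "cluster_id",
                            "canonical_motif", "unit_size")
  }
  list(
    candidates = cand,
    dropped_loci = filt$dropped,
    dropped_clusters = dplyr::bind_rows(dropped_clusters),
    dropped_groups = dplyr::bind_rows(dropped_groups),
    n_groups = n_groups
  )
}
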