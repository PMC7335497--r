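# Per-cluster multiple sequence alignment (centre-star) and result files.
# The representative (longest member) is the centre; each other member is
# aligned to it with the package's deterministic affine-gap aligner
# (match +1, mismatch -1, gap open -4, gap extend -1) and the pairwise
# alignments are merged "once a gap, always a gap".

#' Centre-star multiple alignment of a cluster
#'
#' Aligns every member of a strand-normalised cluster to the
#' representative with [align_pair()] and merges the pairwise alignments
#' once-a-gap-always-a-gap.  Repeat loci are mapped to alignment columns
#' so their position can be inspected across members.
#'
#' @param cluster_members Cluster tibble rows for one cluster (>= 2
#'   members, strand-normalised).
#' @param transcripts Normalised transcript tibble.
#' @param loci Normalised locus tibble (may be empty).
#' @return A list of class `aligned_cluster`: `cluster_id`, `alignment`
#'   (tibble `source_tag`, `seq_id`, `aligned` - equal-length gapped
#'   strings, representative first) and `ssr_columns` (tibble `source_tag`,
#'   `seq_id`, `canonical_motif`, `col_start`, `col_end`).
#' @export
align_cluster <- function(cluster_members, transcripts, loci = NULL) {
  stopifnot(is.data.frame(cluster_members), is.data.frame(transcripts))
  if (nrow(cluster_members) < 2L) {
    stop("alignment needs a cluster with at least two members",
         call. = FALSE)
  }
  if ("strand" %in% names(cluster_members) &&
      any(cluster_members$strand == "-")) {
    stop("cluster must be strand-normalised before alignment", call. = FALSE)
  }
  key <- function(tag, id) paste(tag, id, sep = "\r")
  tx_key <- key(transcripts$source_tag, transcripts$seq_id)
  m <- cluster_members[order(-as.integer(cluster_members$is_representative)), ,
                       drop = FALSE]
  seqs <- transcripts$sequence[match(key(m$source_tag, m$seq_id), tx_key)]
  if (anyNA(seqs)) {
    stop("cluster member(s) missing from the transcript table", call. = FALSE)
  }
  center <- seqs[1L]
  n_center <- nchar(center)

  # For each member alignment, record the centre-gap profile: number of
  # member bases inserted before each centre position (and after the last).
  n_members <- length(seqs) - 1L
  member_rows <- vector("list", n_members)
  insert_before <- matrix(0L, nrow = max(n_members, 1L), ncol = n_center + 1L)
  for (i in seq_len(n_members)) {
    aln <- align_pair(center, seqs[i + 1L])
    ca <- strsplit(aln$a, "", fixed = TRUE)[[1L]]
    ma <- strsplit(aln$b, "", fixed = TRUE)[[1L]]
    pos <- 0L
    pieces <- character(n_center + 1L) # member bases between centre bases
    pieces[] <- ""
    aligned_to <- character(n_center)  # member char aligned to centre pos
    for (col in seq_along(ca)) {
      if (ca[col] == "-") {
        pieces[pos + 1L] <- paste0(pieces[pos + 1L], ma[col])
      } else {
        pos <- pos + 1L
        aligned_to[pos] <- ma[col]
      }
    }
    insert_before[i, ] <- nchar(pieces)
    member_rows[[i]] <- list(pieces = pieces, aligned_to = aligned_to)
  }
  max_insert <- if (n_members > 0L) {
    apply(insert_before, 2L, max)
  } else {
    integer(n_center + 1L)
  }

  pad <- function(s, width) paste0(s, strrep("-", width - nchar(s)))
  build_row <- function(pieces, aligned_to) {
    segs <- character(2L * n_center + 1L)
    segs[1L] <- pad(pieces[1L], max_insert[1L])
    for (p in seq_len(n_center)) {
      segs[2L * p] <- aligned_to[p]
      segs[2L * p + 1L] <- pad(pieces[p + 1L], max_insert[p + 1L])
    }
    paste(segs, collapse = "")
  }
  center_row <- build_row(rep("", n_center + 1L),
                          strsplit(center, "", fixed = TRUE)[[1L]])
  rows <- c(center_row, vapply(member_rows, function(mr) {
    build_row(mr$pieces, mr$aligned_to)
  }, character(1)))

  alignment <- tibble::tibble(
    source_tag = m$source_tag, seq_id = m$seq_id, aligned = rows
  )

  ssr_columns <- tibble::tibble(
    source_tag = character(), seq_id = character(),
    canonical_motif = character(), col_start = integer(),
    col_end = integer()
  )
  if (!is.null(loci) && nrow(loci) > 0L) {
    mk <- key(m$source_tag, m$seq_id)
    sel <- key(loci$source_tag, loci$seq_id) %in% mk
    ll <- loci[sel, , drop = FALSE]
    if (nrow(ll) > 0L) {
      spans <- purrr::pmap(
        list(ll$source_tag, ll$seq_id, ll$start, ll$end, ll$canonical_motif),
        function(tag, id, s, e, cm) {
          row <- rows[match(key(tag, id), mk)]
          chars <- strsplit(row, "", fixed = TRUE)[[1L]]
          base_cols <- which(chars != "-")
          tibble::tibble(source_tag = tag, seq_id = id,
                         canonical_motif = cm,
                         col_start = base_cols[s], col_end = base_cols[e])
        }
      )
      ssr_columns <- dplyr::bind_rows(spans)
    }
  }
  structure(
    list(cluster_id = cluster_members$cluster_id[1L], alignment = alignment,
         ssr_columns = ssr_columns),
    class = "aligned_cluster"
  )
}

#' Write pipeline result files
#'
#' Writes (a) the candidate table as TSV, (b) one aligned-FASTA file per
#' candidate cluster (gaps as `-`, headers `source_tag|seq_id|strand`)
#' under `alignments/`, and (c) a plain-text run summary with counts per
#' pipeline stage and the full effective configuration.  Outputs are
#' byte-identical across runs with the same inputs and configuration.
#'
#' @param result A `ssr_enrichment` object from [run_ssr_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "ssr_enrichment"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  readr::write_tsv(result$candidates, file.path(out_dir, "candidates.tsv"))
  readr::write_tsv(result$loci, file.path(out_dir, "ssr_loci.tsv"))
  readr::write_tsv(result$clusters, file.path(out_dir, "clusters.tsv"))

  aln_dir <- file.path(out_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  strands <- result$clusters
  for (ac in result$alignments) {
    lines <- character(0)
    for (r in seq_len(nrow(ac$alignment))) {
      tag <- ac$alignment$source_tag[r]
      id <- ac$alignment$seq_id[r]
      strand <- strands$input_strand[strands$source_tag == tag &
                                       strands$seq_id == id][1L]
      lines <- c(lines, paste0(">", tag, "|", id, "|", strand),
                 ac$alignment$aligned[r])
    }
    writeLines(lines, file.path(aln_dir,
                                sprintf("cluster_%04d.afa", ac$cluster_id)))
  }

  cnt <- result$counts
  cfg <- result$config
  fmt_params <- function(x) {
    paste0("  ", names(x), " = ",
           vapply(x, function(v) paste(as.character(v), collapse = ","),
                  character(1)),
           collapse = "\n")
  }
  summary_lines <- c(
    "polyssr run summary",
    "===================",
    sprintf("records read:                %d", cnt$n_records),
    sprintf("SSR loci mined:              %d", cnt$n_loci),
    sprintf("clusters formed:             %d", cnt$n_clusters),
    sprintf("loci dropped by filters:     %d", cnt$n_dropped_loci),
    sprintf("clusters dropped (false +):  %d", cnt$n_dropped_clusters),
    sprintf("locus groups matched:        %d", cnt$n_groups),
    sprintf("candidates emitted:          %d", cnt$n_candidates),
    "",
    "configuration",
    "-------------",
    "mining_thresholds:", fmt_params(cfg$thresholds),
    "cluster_params:", fmt_params(cfg$cluster_params),
    "enrichment_params:", fmt_params(cfg$enrichment_params)
  )
  writeLines(summary_lines, file.path(out_dir, "run_summary.txt"))
  invisible(out_dir)
}
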