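# Greedy cross-sample clustering in the CD-HIT-EST spirit: records are
# processed longest-first and either join the best-matching existing
# representative at >= identity_threshold (considering both strands) or
# found a new cluster.  Exact CD-HIT internals (short-word heuristics,
# first-fit assignment) are intentionally not replicated; the identity
# definition (aligned matches / shorter length, end gaps free) and best-fit
# assignment make the procedure deterministic and independently checkable.

KMER_LEN <- 11L

seq_kmers <- function(sequence) {
  n <- nchar(sequence)
  if (n < KMER_LEN) return(character(0))
  unique(substring(sequence, seq_len(n - KMER_LEN + 1L),
                   seq.int(KMER_LEN, n)))
}

#' Cluster transcripts across samples
#'
#' Groups transcripts from all input samples at `identity_threshold`
#' (default 0.90) considering both strands.  Records are processed in
#' decreasing length order (ties by `source_tag`, `seq_id`), so permuting
#' the input rows never changes the result.  Each record joins the
#' existing cluster whose representative gives the highest identity at or
#' above the threshold (ties to the lowest cluster id), else it founds a
#' new cluster; the representative of a cluster is therefore always its
#' longest member.  Clusters with fewer than `min_members` members are
#' dropped, since a repeat-count comparison needs at least two homologs.
#'
#' A shared-11-mer prescreen skips alignments against representatives that
#' cannot plausibly reach the threshold; see [cluster_params()].
#'
#' @param transcripts Tibble of transcripts from all samples.
#' @param params A [cluster_params()] object.
#' @return A tibble with one row per cluster member: `cluster_id`,
#'   `source_tag`, `seq_id`, `length`, `strand` (orientation relative to
#'   the representative), `identity` (to the representative; 1 for the
#'   representative itself) and `is_representative`.  Cluster ids are
#'   consecutive integers in founding order.
#' @export
cluster_transcripts <- function(transcripts, params = cluster_params()) {
  stopifnot(is.data.frame(transcripts), inherits(params, "cluster_params"))
  if (nrow(transcripts) == 0L) stop("no transcripts to cluster", call. = FALSE)
  ord <- order(-transcripts$length, transcripts$source_tag,
               transcripts$seq_id, method = "radix")
  tx <- transcripts[ord, , drop = FALSE]

  rep_idx <- integer(0)        # row in tx of each representative
  rep_kmers <- list()          # forward k-mer set of each representative
  assign_cluster <- integer(nrow(tx))
  assign_strand <- character(nrow(tx))
  assign_identity <- numeric(nrow(tx))

  for (i in seq_len(nrow(tx))) {
    seq_i <- tx$sequence[i]
    n_rep <- length(rep_idx)
    best_id <- 0
    best_cluster <- NA_integer_
    best_strand <- "+"
    if (n_rep > 0L) {
      if (nchar(seq_i) >= 100L) {
        km <- seq_kmers(seq_i)
        if (params$compare_both_strands) {
          km <- unique(c(km, seq_kmers(reverse_complement(seq_i))))
        }
        candidates <- which(vapply(rep_kmers, function(set) {
          sum(km %in% set) >= params$min_shared_kmers
        }, logical(1)))
      } else {
        candidates <- seq_len(n_rep)
      }
      for (cl in candidates) {
        hit <- pairwise_identity(tx$sequence[rep_idx[cl]], seq_i, params)
        if (hit$identity >= params$identity_threshold &&
            hit$identity > best_id) {
          best_id <- hit$identity
          best_cluster <- cl
          best_strand <- hit$strand
        }
      }
    }
    if (is.na(best_cluster)) {
      rep_idx <- c(rep_idx, i)
      rep_kmers[[length(rep_idx)]] <- seq_kmers(seq_i)
      assign_cluster[i] <- length(rep_idx)
      assign_strand[i] <- "+"
      assign_identity[i] <- 1
    } else {
      assign_cluster[i] <- best_cluster
      assign_strand[i] <- best_strand
      assign_identity[i] <- best_id
    }
  }

  out <- tibble::tibble(
    cluster_id = assign_cluster,
    source_tag = tx$source_tag,
    seq_id = tx$seq_id,
    length = tx$length,
    strand = assign_strand,
    identity = assign_identity,
    is_representative = seq_len(nrow(tx)) %in% rep_idx
  )
  sizes <- table(out$cluster_id)
  keep <- as.integer(names(sizes)[sizes >= params$min_members])
  out <- out[out$cluster_id %in% keep, , drop = FALSE]
  # renumber retained clusters consecutively, preserving founding order
  out$cluster_id <- match(out$cluster_id, sort(unique(out$cluster_id)))
  dplyr::arrange(out, .data$cluster_id, dplyr::desc(.data$is_representative),
                 dplyr::desc(.data$length), .data$source_tag, .data$seq_id)
}

#' Flip a repeat locus onto the opposite strand
#'
#' Recomputes locus coordinates and motif after a sequence of length
#' `seq_length` is reverse-complemented: `start' = L - end + 1`,
#' `end' = L - start + 1`, motif reverse-complemented, canonical motif
#' recomputed.  Repeat count and unit size are unchanged; flipping twice
#' returns the original locus.
#'
#' @param loci Locus tibble (any subset of rows from [find_ssrs()]).
#' @param seq_length Length of the sequence the loci sit on (one value, or
#'   one per row).
#' @return The flipped locus tibble.
#' @export
flip_locus <- function(loci, seq_length) {
  stopifnot(is.data.frame(loci))
  if (nrow(loci) == 0L) return(loci)
  L <- as.integer(seq_length)
  if (any(loci$start < 1L) || any(loci$end > L) ||
      any(loci$start > loci$end)) {
    stop("locus coordinates out of range for the sequence length",
         call. = FALSE)
  }
  new_start <- L - loci$end + 1L
  new_end <- L - loci$start + 1L
  loci$start <- new_start
  loci$end <- new_end
  loci$motif <- reverse_complement(loci$motif)
  loci$canonical_motif <- canonical_motif(loci$motif)
  loci[order(loci$start), , drop = FALSE]
}

#' Re-orient cluster members onto the representative's strand
#'
#' Every member assigned strand `-` has its sequence replaced by the
#' reverse complement and its repeat loci transformed with [flip_locus()];
#' afterwards all members of every cluster are co-oriented.  The original
#' orientation is preserved in the `input_strand` column of the returned
#' cluster table.  The operation is idempotent.
#'
#' @param transcripts Transcript tibble covering every cluster member.
#' @param clusters Cluster tibble from [cluster_transcripts()].
#' @param loci Locus tibble from [find_ssrs()] covering every member (a
#'   member with zero mined loci is fine; a member record missing from
#'   `transcripts` is an error).
#' @return A list with elements `transcripts`, `clusters` and `loci`, all
#'   updated.
#' @export
normalize_strands <- function(transcripts, clusters, loci) {
  stopifnot(is.data.frame(transcripts), is.data.frame(clusters),
            is.data.frame(loci))
  key <- function(tag, id) paste(tag, id, sep = "\r")
  tx_key <- key(transcripts$source_tag, transcripts$seq_id)
  member_key <- key(clusters$source_tag, clusters$seq_id)
  missing <- setdiff(member_key, tx_key)
  if (length(missing) > 0L) {
    stop("cluster member(s) missing from the transcript table",
         call. = FALSE)
  }
  if (!"input_strand" %in% names(clusters)) {
    clusters$input_strand <- clusters$strand
  }
  neg <- member_key[clusters$strand == "-"]
  if (length(neg) > 0L) {
    rows <- match(neg, tx_key)
    transcripts$sequence[rows] <-
      reverse_complement(transcripts$sequence[rows])
    loci_key <- key(loci$source_tag, loci$seq_id)
    for (r in rows) {
      k <- tx_key[r]
      hit <- which(loci_key == k)
      if (length(hit) > 0L) {
        loci[hit, ] <- flip_locus(loci[hit, , drop = FALSE],
                                  transcripts$length[r])
      }
    }
    clusters$strand[clusters$strand == "-"] <- "+"
  }
  loci <- dplyr::arrange(loci, .data$source_tag, .data$seq_id, .data$start)
  list(transcripts = transcripts, clusters = clusters, loci = loci)
}

#' Write a CD-HIT-style cluster report
#'
#' Plain-text layout resembling `.clstr` files: a `>Cluster n` header line
#' followed by one member per line with length, id, strand and identity
#' percentage (the representative is marked `*`).
#'
#' @param clusters Cluster tibble from [cluster_transcripts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  stopifnot(is.data.frame(clusters))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cid in unique(clusters$cluster_id)) {
    writeLines(sprintf(">Cluster %d", cid), con)
    m <- clusters[clusters$cluster_id == cid, , drop = FALSE]
    lines <- ifelse(
      m$is_representative,
      sprintf("%d\t%dnt, >%s|%s... *", seq_len(nrow(m)) - 1L, m$length,
              m$source_tag, m$seq_id),
      sprintf("%d\t%dnt, >%s|%s... at %s/%.2f%%", seq_len(nrow(m)) - 1L,
              m$length, m$source_tag, m$seq_id, m$strand,
              100 * m$identity)
    )
    writeLines(lines, con)
  }
  invisible(path)
}
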