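#' Run the full polymorphic-SSR discovery pipeline
#'
#' Executes the whole pipeline - read, mine, cluster, strand-normalise,
#' enrich, align, report - over two or more samples and returns a
#' `ssr_enrichment` object.  Identical inputs and configuration produce
#' identical results (and byte-identical output files), regardless of the
#' order in which the input files are given.
#'
#' @param inputs Character vector of >= 2 FASTA paths (one per
#'   sample/ecotype), or a transcript tibble with >= 2 distinct
#'   `source_tag` values (e.g. from [simulate_transcripts()]).
#' @param out_dir Optional output directory; when supplied, result files
#'   are written via [write_outputs()].
#' @param thresholds A [mining_thresholds()] object.
#' @param clustering A [cluster_params()] object.
#' @param enrichment An [enrichment_params()] object.
#' @param align Compute per-cluster multiple alignments for candidate
#'   clusters (default `TRUE`).
#' @return An object of class `ssr_enrichment`: a list with `transcripts`
#'   and `loci` (strand-normalised), `clusters`, `candidates`,
#'   `dropped_loci`, `dropped_clusters`, `dropped_groups`, `alignments`
#'   (list of `aligned_cluster` for clusters with candidates), `counts`
#'   (per-stage tallies) and `config`.
#' @examples
#' sim <- simulate_transcripts(simulation_config(n_families = 15,
#'                                               rng_seed = 7))
#' res <- run_ssr_pipeline(sim$transcripts)
#' glance(res)
#' @export
run_ssr_pipeline <- function(inputs,
                             out_dir = NULL,
                             thresholds = mining_thresholds(),
                             clustering = cluster_params(),
                             enrichment = enrichment_params(),
                             align = TRUE) {
  stopifnot(inherits(thresholds, "mining_thresholds"),
            inherits(clustering, "cluster_params"),
            inherits(enrichment, "enrichment_params"))
  if (is.character(inputs)) {
    if (length(inputs) < 2L) {
      stop("cross-sample comparison needs at least two input files",
           call. = FALSE)
    }
    transcripts <- read_transcript_set(inputs)
  } else if (is.data.frame(inputs)) {
    transcripts <- inputs
    if (dplyr::n_distinct(transcripts$source_tag) < 2L) {
      stop("cross-sample comparison needs transcripts from at least two ",
           "samples (source tags)", call. = FALSE)
    }
  } else {
    stop("`inputs` must be FASTA paths or a transcript tibble",
         call. = FALSE)
  }

  loci <- find_ssrs(transcripts, thresholds)
  clusters <- cluster_transcripts(transcripts, clustering)
  norm <- normalize_strands(transcripts, clusters, loci)
  enr <- enrich_candidates(norm$clusters, norm$transcripts, norm$loci,
                           enrichment)

  alignments <- list()
  if (align && nrow(enr$candidates) > 0L) {
    for (cid in unique(enr$candidates$cluster_id)) {
      members <- norm$clusters[norm$clusters$cluster_id == cid, ,
                               drop = FALSE]
      alignments[[length(alignments) + 1L]] <-
        align_cluster(members, norm$transcripts, norm$loci)
    }
  }

  result <- structure(
    list(
      transcripts = norm$transcripts,
      loci = norm$loci,
      clusters = norm$clusters,
      candidates = enr$candidates,
      dropped_loci = enr$dropped_loci,
      dropped_clusters = enr$dropped_clusters,
      dropped_groups = enr$dropped_groups,
      alignments = alignments,
      counts = list(
        n_records = nrow(transcripts),
        n_loci = nrow(loci),
        n_clusters = dplyr::n_distinct(clusters$cluster_id),
        n_dropped_loci = nrow(enr$dropped_loci),
        n_dropped_clusters = nrow(enr$dropped_clusters),
        n_groups = enr$n_groups,
        n_candidates = dplyr::n_distinct(enr$candidates$candidate_id)
      ),
      config = list(thresholds = thresholds,
                    cluster_params = clustering,
                    enrichment_params = enrichment)
    ),
    class = "ssr_enrichment"
  )
  if (!is.null(out_dir)) write_outputs(result, out_dir)
  result
}

#' @export
print.ssr_enrichment <- function(x, ...) {
  cnt <- x$counts
  cat("Polymorphic-SSR enrichment\n")
  cat(sprintf("  transcripts: %d  (samples: %s)\n", cnt$n_records,
              paste(unique(x$transcripts$source_tag), collapse = ", ")))
  cat(sprintf("  SSR loci mined: %d (dropped by filters: %d)\n",
              cnt$n_loci, cnt$n_dropped_loci))
  cat(sprintf("  clusters: %d (dropped as false positives: %d)\n",
              cnt$n_clusters, cnt$n_dropped_clusters))
  cat(sprintf("  candidate polymorphic loci: %d\n", cnt$n_candidates))
  invisible(x)
}

#' Tidy the candidate table of a pipeline result
#'
#' @param x A `ssr_enrichment` object.
#' @param ... Unused.
#' @return The candidate tibble (one row per member locus per candidate).
#' @export
tidy.ssr_enrichment <- function(x, ...) {
  x$candidates
}

#' One-row summary of a pipeline run
#'
#' @param x A `ssr_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble with per-stage counts.
#' @export
glance.ssr_enrichment <- function(x, ...) {
  tibble::as_tibble(x$counts)
}

#' Plot a summary of candidate polymorphic repeats
#'
#' Bar chart of candidate loci by canonical motif, filled by the maximum
#' cross-member repeat-count difference.
#'
#' @param object A `ssr_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssr_enrichment <- function(object, ...) {
  cand <- object$candidates
  if (nrow(cand) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No candidate polymorphic SSRs") +
             ggplot2::theme_minimal())
  }
  per_cand <- cand |>
    dplyr::distinct(.data$candidate_id, .data$canonical_motif,
                    .data$unit_size, .data$max_repeat_difference)
  ggplot2::ggplot(per_cand,
                  ggplot2::aes(x = .data$canonical_motif,
                               fill = factor(.data$max_repeat_difference))) +
    ggplot2::geom_bar() +
    ggplot2::facet_grid(~ .data$unit_size, scales = "free_x",
                        space = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "canonical motif", y = "candidate loci",
                  fill = "max repeat\ndifference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
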