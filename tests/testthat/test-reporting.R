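norm_pipeline <- function(tx) {
  loci <- find_ssrs(tx)
  cl <- cluster_transcripts(tx)
  normalize_strands(tx, cl, loci)
}

test_that("centre-star alignment handles identity and single deletions", {
  set.seed(61)
  a <- rand_dna(120)
  tx <- dplyr::bind_rows(make_tx(a, "eco1", "s1"), make_tx(a, "eco2", "s2"))
  norm <- norm_pipeline(tx)
  ac <- align_cluster(norm$clusters, norm$transcripts, norm$loci)
  expect_equal(ac$alignment$aligned[1], ac$alignment$aligned[2])
  expect_false(grepl("-", ac$alignment$aligned[1], fixed = TRUE))

  b <- paste0(substr(a, 1, 60), substr(a, 62, 120)) # one deletion
  tx <- dplyr::bind_rows(make_tx(a, "eco1", "s1"), make_tx(b, "eco2", "s2"))
  norm <- norm_pipeline(tx)
  ac <- align_cluster(norm$clusters, norm$transcripts, norm$loci)
  member_row <- ac$alignment$aligned[ac$alignment$seq_id == "s2"]
  expect_equal(sum(strsplit(member_row, "")[[1]] == "-"), 1L)
  expect_error(align_cluster(norm$clusters[1, ], norm$transcripts), "two")
})

test_that("repeat-length differences align as gaps inside the repeat span", {
  set.seed(62)
  up <- rand_dna(80); down <- rand_dna(80)
  tx <- dplyr::bind_rows(
    make_tx(paste0(up, strrep("AC", 10), down), "eco1", "s1"),
    make_tx(paste0(up, strrep("AC", 8), down), "eco2", "s2")
  )
  norm <- norm_pipeline(tx)
  ac <- align_cluster(norm$clusters, norm$transcripts, norm$loci)
  short_row <- ac$alignment$aligned[ac$alignment$seq_id == "s2"]
  gaps <- which(strsplit(short_row, "")[[1]] == "-")
  expect_equal(length(gaps), 4L)
  centre_span <- ac$ssr_columns[ac$ssr_columns$seq_id == "s1", ]
  expect_true(all(gaps >= centre_span$col_start - 1 &
                    gaps <= centre_span$col_end + 1))
})

test_that("de-gapping each aligned row reproduces the member sequences, and
           ssr column spans reproduce the locus intervals", {
  sim <- simulate_transcripts(simulation_config(n_families = 10,
                                                rng_seed = 63))
  res <- run_ssr_pipeline(sim$transcripts)
  key <- paste(res$transcripts$source_tag, res$transcripts$seq_id, sep = "|")
  for (ac in res$alignments) {
    widths <- nchar(ac$alignment$aligned)
    expect_equal(length(unique(widths)), 1L)
    for (r in seq_len(nrow(ac$alignment))) {
      degapped <- gsub("-", "", ac$alignment$aligned[r], fixed = TRUE)
      expect_equal(degapped, res$transcripts$sequence[
        match(paste(ac$alignment$source_tag[r], ac$alignment$seq_id[r],
                    sep = "|"), key)])
    }
    for (r in seq_len(nrow(ac$ssr_columns))) {
      span <- ac$ssr_columns[r, ]
      row <- ac$alignment$aligned[
        ac$alignment$source_tag == span$source_tag &
          ac$alignment$seq_id == span$seq_id]
      piece <- gsub("-", "",
                    substr(row, span$col_start, span$col_end), fixed = TRUE)
      locus <- res$loci[res$loci$source_tag == span$source_tag &
                          res$loci$seq_id == span$seq_id &
                          res$loci$canonical_motif == span$canonical_motif, ]
      expect_true(any(piece ==
                        strrep(locus$motif, locus$repeat_count)))
    }
  }
})

test_that("member-to-centre scores equal the independent DP oracle", {
  sim <- simulate_transcripts(simulation_config(n_families = 4,
                                                length_range = c(250L, 300L),
                                                rng_seed = 64))
  res <- run_ssr_pipeline(sim$transcripts)
  expect_gte(length(res$alignments), 1L)
  key <-paste(res$transcripts$source_tag, res$transcripts$seq_id, sep = "|")
  for (ac in res$alignments) {
    seqs <- res$transcripts$sequence[
      match(paste(ac$alignment$source_tag, ac$alignment$seq_id, sep = "|"),
            key)]
    for (i in seq_along(seqs)[-1]) {
      expect_equal(align_pair(seqs[1], seqs[i])$score,
                   bios_global_score(seqs[1], seqs[i]))
    }
  }
})

test_that("output files: inventory, empty-result contract, stage consistency", {
  sim <- simulate_transcripts(simulation_config(n_families = 12,
                                                rng_seed = 65))
  out <- withr::local_tempdir()
  res <- run_ssr_pipeline(sim$transcripts, out_dir = out)
  expect_true(file.exists(file.path(out, "candidates.tsv")))
  expect_true(file.exists(file.path(out, "run_summary.txt")))
  aln_files <- list.files(file.path(out, "alignments"), pattern = "\\.afa$")
  expect_equal(length(aln_files),
               dplyr::n_distinct(res$candidates$cluster_id))
  for (cid in unique(res$candidates$cluster_id)) {
    expect_true(any(grepl(sprintf("%04d", cid), aln_files)))
  }
  # stage counts are monotone: candidates <= groups <= clusters' loci
  expect_lte(res$counts$n_candidates, res$counts$n_groups)
  expect_lte(res$counts$n_dropped_clusters, res$counts$n_clusters)
  summary_txt <- readLines(file.path(out, "run_summary.txt"))
  expect_true(any(grepl("identity_threshold = 0.9", summary_txt)))

  # zero-candidate run still writes a header-only candidate table
  tx <- dplyr::bind_rows(
    make_tx(rand_dna(300), "eco1", "a"),
    make_tx(rand_dna(300), "eco2", "b")
  )
  out2 <- withr::local_tempdir()
  res2 <- run_ssr_pipeline(tx, out_dir = out2)
  expect_equal(res2$counts$n_candidates, 0L)
  cand_lines <- readLines(file.path(out2, "candidates.tsv"))
  expect_equal(length(cand_lines), 1L)
  expect_true(any(grepl("candidates emitted:          0",
                        readLines(file.path(out2, "run_summary.txt")))))
})
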