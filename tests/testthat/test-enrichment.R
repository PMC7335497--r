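# helper: a two-member cluster tibble for hand-built sequences
two_member_cluster <- function(tx) {
  tibble::tibble(
    cluster_id = 1L, source_tag = tx$source_tag, seq_id = tx$seq_id,
    length = tx$length, strand = "+",
    identity = c(1, rep(0.95, nrow(tx) - 1L)),
    is_representative = c(TRUE, rep(FALSE, nrow(tx) - 1L))
  )
}

test_that("flank and mononucleotide filters apply the documented boundaries", {
  set.seed(50)
  params <- enrichment_params()
  # guard bases ("A" next to a GT run, "C" next to a poly-A run) pin the
  # planted runs so random flanks cannot extend them
  # mononucleotide run with comfortable flanks is still removed
  tx <- make_tx(paste0(rand_dna(199), "C", strrep("A", 12), "C",
                       rand_dna(199)))
  loci <- find_ssrs(tx)
  out <- filter_loci(loci, tx, params)
  expect_equal(nrow(out$kept), 0L)
  expect_equal(out$dropped$reason, "mononucleotide")
  # left flank of 29 fails the 50 bp rule
  tx <- make_tx(paste0(rand_dna(28), "A", strrep("GT", 7), "A",
                       rand_dna(399)))
  out <- filter_loci(find_ssrs(tx), tx, params)
  expect_equal(out$dropped$reason[out$dropped$unit_size == 2L], "flank")
  expect_false(any(out$kept$unit_size == 2L))
  # flanks of exactly 50 on both sides pass
  tx <- make_tx(paste0(rand_dna(49), "A", strrep("GT", 7), "A",
                       rand_dna(49)))
  out <- filter_loci(find_ssrs(tx), tx, params)
  expect_equal(nrow(out$kept), 1L)
  expect_equal(out$kept$left_flank, 50L)
  expect_equal(out$kept$right_flank, 50L)
})

test_that("the paralogy screen drops exactly the clusters the rule names", {
  count_tab <- function(...) {
    # build loci rows from per-member motif counts
    spec <- list(...)
    rows <- list()
    for (m in seq_along(spec)) {
      for (motif in names(spec[[m]])) {
        n <- spec[[m]][[motif]]
        if (n > 0L) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            seq_id = paste0("s", m), source_tag = paste0("eco", m),
            motif = motif, canonical_motif = motif,
            unit_size = nchar(motif), repeat_count = 8L,
            start = 100L * seq_len(n), end = 100L * seq_len(n) + 7L,
            compound_group = NA_integer_
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  }
  members <- tibble::tibble(source_tag = c("eco1", "eco2"),
                            seq_id = c("s1", "s2"))
  # two (GT) loci vs one: dropped
  res <- screen_false_positive(members, count_tab(list(GT = 2L),
                                                  list(GT = 1L)))
  expect_false(res$keep)
  expect_match(res$reason, "false_positive")
  expect_equal(res$motif, "GT")
  # equal counts: kept
  expect_true(screen_false_positive(members, count_tab(list(GT = 2L),
                                                       list(GT = 2L)))$keep)
  # one GT + one CAG vs one GT: kept (no member has two of the missing motif)
  expect_true(screen_false_positive(
    members, count_tab(list(GT = 1L, CAG = 1L), list(GT = 1L)))$keep)
})

test_that("the paralogy screen matches a literal rule oracle on random tables", {
  set.seed(51)
  motifs <- c("AC", "AG", "AAT")
  for (i in 1:200) {
    n_members <- sample(2:3, 1)
    counts <- matrix(sample(0:3, n_members * 3, replace = TRUE),
                     nrow = n_members, dimnames = list(NULL, motifs))
    members <- tibble::tibble(source_tag = paste0("eco", seq_len(n_members)),
                              seq_id = paste0("s", seq_len(n_members)))
    rows <- list()
    for (m in seq_len(n_members)) {
      for (mo in motifs) {
        n <- counts[m, mo]
        if (n > 0L) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            seq_id = members$seq_id[m], source_tag = members$source_tag[m],
            motif = mo, canonical_motif = mo, unit_size = nchar(mo),
            repeat_count = 8L, start = seq_len(n), end = seq_len(n) + 7L,
            compound_group = NA_integer_
          )[seq_len(n), ]
        }
      }
    }
    loci <- dplyr::bind_rows(rows)
    got <- !screen_false_positive(members, loci)$keep
    expect_equal(got, oracle_false_positive(counts),
                 info = paste(capture.output(print(counts)), collapse = "; "))
  }
})

test_that("locus matching pairs homologs by flanking anchors", {
  set.seed(52)
  up <- rand_dna(60); down <- rand_dna(60)
  tx <- dplyr::bind_rows(
    make_tx(paste0(up, strrep("AC", 8), down), "eco1", "s1"),
    make_tx(paste0(up, strrep("AC", 10), down), "eco2", "s2")
  )
  loci <- filter_loci(find_ssrs(tx), tx)$kept
  groups <- match_loci(two_member_cluster(tx), loci, tx)
  expect_equal(nrow(groups), 2L)
  expect_equal(length(unique(groups$group_id)), 1L)

  # two loci per member at distinct positions pair by anchors, not order
  upA <- rand_dna(60); mid <- rand_dna(150); downB <- rand_dna(60)
  tx2 <- dplyr::bind_rows(
    make_tx(paste0(upA, strrep("AC", 8), mid, strrep("AC", 6), downB),
            "eco1", "s1"),
    make_tx(paste0(upA, strrep("AC", 9), mid, strrep("AC", 7), downB),
            "eco2", "s2")
  )
  loci2 <- filter_loci(find_ssrs(tx2), tx2)$kept
  groups2 <- match_loci(two_member_cluster(tx2), loci2, tx2)
  expect_equal(length(unique(groups2$group_id)), 2L)
  for (g in unique(groups2$group_id)) {
    grp <- groups2[groups2$group_id == g, ]
    expect_equal(nrow(grp), 2L)
    # anchored pairing: both members of a group sit at the same planted
    # position (first repeat with first, second with second)
    expect_lt(abs(grp$start[1] - grp$start[2]), 10L)
  }

  # anchors differing beyond the mismatch budget on both sides: no group
  tx3 <- dplyr::bind_rows(
    make_tx(paste0(rand_dna(60), strrep("AC", 8), rand_dna(60)),
            "eco1", "s1"),
    make_tx(paste0(rand_dna(60), strrep("AC", 8), rand_dna(60)),
            "eco2", "s2")
  )
  loci3 <- filter_loci(find_ssrs(tx3), tx3)$kept
  expect_equal(nrow(match_loci(two_member_cluster(tx3), loci3, tx3)), 0L)

  # unnormalised clusters are rejected
  cl_neg <- two_member_cluster(tx)
  cl_neg$strand[2] <- "-"
  expect_error(match_loci(cl_neg, loci, tx), "strand-normalised")
})

test_that("polymorphism calls follow the repeat-count and cross-file rules", {
  grp <- tibble::tibble(source_tag = c("eco1", "eco2"),
                        seq_id = c("a", "b"), repeat_count = c(8L, 10L),
                        compound_group = NA_integer_)
  call <- detect_polymorphic(grp)
  expect_true(call$polymorphic)
  expect_equal(call$max_repeat_difference, 2L)
  expect_false(call$inside_compound)

  grp$repeat_count <- c(8L, 8L)
  call <- detect_polymorphic(grp)
  expect_false(call$polymorphic)
  expect_equal(call$reason, "no_repeat_difference")

  grp <- tibble::tibble(source_tag = c("eco1", "eco1"),
                        seq_id = c("a", "a2"), repeat_count = c(8L, 10L),
                        compound_group = NA_integer_)
  call <- detect_polymorphic(grp)
  expect_false(call$polymorphic)
  expect_equal(call$reason, "within_file_only")
  call <- detect_polymorphic(grp,
                             enrichment_params(require_cross_file = FALSE))
  expect_true(call$polymorphic)

  grp$compound_group <- c(3L, NA)
  expect_true(detect_polymorphic(
    grp, enrichment_params(require_cross_file = FALSE))$inside_compound)
})

test_that("enrichment end-to-end: happy path, near-end and paralog decoys", {
  set.seed(53)
  # guard bases: "T" differs from both ends of the AGC unit, so the random
  # flanks can never extend a planted run by a whole unit
  up <- paste0(rand_dna(119), "T"); down <- paste0("T", rand_dna(118), "T")
  build <- function(count, extra = "") {
    paste0(up, strrep("AGC", count), down, extra)
  }
  run_enrich <- function(tx) {
    loci <- find_ssrs(tx)
    cl <- cluster_transcripts(tx)
    norm <- normalize_strands(tx, cl, loci)
    enrich_candidates(norm$clusters, norm$transcripts, norm$loci)
  }
  tx <- dplyr::bind_rows(make_tx(build(8), "eco1", "s1"),
                         make_tx(build(10), "eco2", "s2"))
  enr <- run_enrich(tx)
  expect_equal(length(unique(enr$candidates$candidate_id)), 1L)
  expect_equal(sort(enr$candidates$repeat_count), c(8L, 10L))
  expect_equal(enr$candidates$canonical_motif, c("AGC", "AGC"))

  # same cluster but the locus 30 bp from the 5' end: no candidates
  tx_near <- dplyr::bind_rows(
    make_tx(paste0(substr(up, 1, 30), strrep("AGC", 8), down), "eco1", "s1"),
    make_tx(paste0(substr(up, 1, 30), strrep("AGC", 10), down), "eco2", "s2")
  )
  enr <- run_enrich(tx_near)
  expect_equal(nrow(enr$candidates), 0L)
  expect_true(all(enr$dropped_loci$reason == "flank"))

  # paralog decoy: duplicated same-motif locus in one member only
  tail <- rand_dna(80)
  tx_par <- dplyr::bind_rows(
    make_tx(paste0(up, strrep("AGC", 8), down, strrep("AGC", 6), tail),
            "eco1", "s1"),
    make_tx(paste0(up, strrep("AGC", 10), down, tail), "eco2", "s2")
  )
  enr <- run_enrich(tx_par)
  expect_equal(nrow(enr$candidates), 0L)
  expect_equal(enr$dropped_clusters$reason,
               "false_positive:same-motif count mismatch")
})

test_that("candidates re-validate against the stored sequences", {
  sim <- simulate_transcripts(simulation_config(n_families = 20,
                                                rng_seed = 54))
  res <- run_ssr_pipeline(sim$transcripts)
  cand <- res$candidates
  key <- paste(res$transcripts$source_tag, res$transcripts$seq_id, sep = "|")
  for (r in seq_len(nrow(cand))) {
    seq <- res$transcripts$sequence[
      match(paste(cand$source_tag[r], cand$seq_id[r], sep = "|"), key)]
    tract <- substr(seq, cand$start[r], cand$end[r])
    expect_equal(tract, strrep(cand$motif[r], cand$repeat_count[r]))
  }
})

test_that("raising min_flank never increases the candidate count", {
  sim <- simulate_transcripts(simulation_config(n_families = 25,
                                                rng_seed = 55))
  n_cands <- vapply(c(30L, 50L, 80L, 150L), function(mf) {
    res <- run_ssr_pipeline(sim$transcripts,
                            enrichment = enrichment_params(min_flank = mf))
    res$counts$n_candidates
  }, integer(1))
  expect_true(all(diff(n_cands) <= 0L))
})
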