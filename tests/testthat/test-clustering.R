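test_that("reverse complement is correct and involutive", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAGG"), "CCTT")
  expect_equal(reverse_complement("AN"), "NT")
  expect_error(reverse_complement("ACGU"), "A,C,G,T,N")
  set.seed(41)
  for (i in 1:20) {
    s <- rand_dna(sample(10:200, 1), n_rate = 0.05)
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("locus flipping mirrors coordinates and is involutive", {
  loci <- find_ssrs(make_tx(paste0(rand_dna(9), strrep("AC", 6),
                                   rand_dna(79))))
  expect_equal(loci$start, 10L)
  flipped <- flip_locus(loci, 100L)
  expect_equal(flipped$start, 100L - loci$end + 1L)
  expect_equal(flipped$end, 100L - loci$start + 1L)
  expect_equal(flipped$motif, "GT")
  expect_equal(flipped$repeat_count, loci$repeat_count)
  back <- flip_locus(flipped, 100L)
  expect_equal(back$start, loci$start)
  expect_equal(back$motif, loci$motif)
  # whole-sequence locus keeps its coordinates
  whole <- find_ssrs(make_tx(strrep("AC", 8)))
  f <- flip_locus(whole, 16L)
  expect_equal(c(f$start, f$end), c(1L, 16L))
  expect_equal(f$motif, "GT")
  expect_error(flip_locus(whole, 10L), "out of range")
})

test_that("greedy clustering assigns by best identity and drops singletons", {
  set.seed(43)
  a <- rand_dna(200)
  b <- mutate_dna(a, 10)   # 95% to a
  c <- rand_dna(200)       # unrelated
  tx <- dplyr::bind_rows(
    make_tx(a, source_tag = "eco1", seq_id = "A"),
    make_tx(b, source_tag = "eco2", seq_id = "B"),
    make_tx(c, source_tag = "eco2", seq_id = "C")
  )
  cl <- cluster_transcripts(tx)
  expect_equal(sort(cl$seq_id), c("A", "B"))
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_gte(min(cl$identity), 0.90)
  # identical sequences from different files form one cluster at 1.0
  tx2 <- dplyr::bind_rows(make_tx(a, "eco1", "A"), make_tx(a, "eco2", "A"))
  cl2 <- cluster_transcripts(tx2)
  expect_equal(cl2$identity, c(1, 1))
  # a sequence and its reverse complement cluster with strand bookkeeping
  tx3 <- dplyr::bind_rows(
    make_tx(a, "eco1", "F"),
    make_tx(reverse_complement(a), "eco2", "R")
  )
  cl3 <- cluster_transcripts(tx3)
  expect_equal(cl3$strand[cl3$seq_id == "R"], "-")
  expect_equal(cl3$identity[cl3$seq_id == "R"], 1)
  expect_true(cl3$is_representative[cl3$seq_id == "F"])
})

test_that("clustering is invariant to input row order", {
  set.seed(44)
  sim <- simulate_transcripts(simulation_config(n_families = 12,
                                                substitution_rate = 0.03,
                                                rng_seed = 9))
  tx <- sim$transcripts
  cl1 <- cluster_transcripts(tx)
  cl2 <- cluster_transcripts(tx[sample(nrow(tx)), ])
  expect_identical(cl1, cl2)
})

test_that("planted families are recovered exactly and identities re-verify", {
  sim <- simulate_transcripts(simulation_config(n_families = 25,
                                                substitution_rate = 0.05,
                                                negative_strand_rate = 0.2,
                                                rng_seed = 17))
  cl <- cluster_transcripts(sim$transcripts)
  expect_identical(cluster_partition(cl), family_partition(sim$transcripts))
  # re-check every member against its representative with the independent
  # Biostrings engine (reverse-complementing "-" members first)
  key <- paste(sim$transcripts$source_tag, sim$transcripts$seq_id, sep = "|")
  for (cid in unique(cl$cluster_id)) {
    m <- cl[cl$cluster_id == cid, ]
    rep_seq <- sim$transcripts$sequence[
      match(paste(m$source_tag[m$is_representative],
                  m$seq_id[m$is_representative], sep = "|"), key)]
    for (r in which(!m$is_representative)) {
      s <- sim$transcripts$sequence[
        match(paste(m$source_tag[r], m$seq_id[r], sep = "|"), key)]
      if (m$strand[r] == "-") s <- reverse_complement(s)
      expect_gte(bios_overlap_identity(rep_seq, s), 0.90)
    }
  }
})

test_that("min_members controls which clusters are returned", {
  set.seed(46)
  a <- rand_dna(150)
  tx <- dplyr::bind_rows(make_tx(a, "eco1", "A"),
                         make_tx(rand_dna(150), "eco2", "B"))
  expect_equal(nrow(cluster_transcripts(tx)), 0L)
  cl <- cluster_transcripts(tx, cluster_params(min_members = 1L))
  expect_equal(nrow(cl), 2L)
  expect_equal(length(unique(cl$cluster_id)), 2L)
})

test_that("strand normalisation co-orients members and flips loci", {
  set.seed(47)
  backbone <- paste0(rand_dna(80), strrep("AC", 8), rand_dna(80))
  tx <- dplyr::bind_rows(
    make_tx(paste0(backbone, rand_dna(20)), "eco1", "P"), # longer: representative
    make_tx(reverse_complement(backbone), "eco2", "M")
  )
  loci <- find_ssrs(tx)
  cl <- cluster_transcripts(tx)
  expect_equal(cl$strand[cl$seq_id == "M"], "-")
  norm <- normalize_strands(tx, cl, loci)
  expect_true(all(norm$clusters$strand == "+"))
  expect_equal(norm$clusters$input_strand[norm$clusters$seq_id == "M"], "-")
  expect_equal(norm$transcripts$sequence[norm$transcripts$seq_id == "M"],
               backbone)
  m_locus <- norm$loci[norm$loci$seq_id == "M", ]
  expect_equal(m_locus$motif, "AC")
  expect_equal(m_locus$start, 81L)
  # idempotent, and a no-op for all-plus clusters
  norm2 <- normalize_strands(norm$transcripts, norm$clusters, norm$loci)
  expect_identical(norm2$transcripts, norm$transcripts)
  expect_identical(norm2$loci, norm$loci)
  expect_error(normalize_strands(tx[1, ], cl, loci), "missing")
})

test_that("cluster report lists every member under its cluster header", {
  set.seed(48)
  a <- rand_dna(120)
  tx <- dplyr::bind_rows(make_tx(a, "eco1", "A"),
                         make_tx(mutate_dna(a, 5), "eco2", "B"))
  cl <- cluster_transcripts(tx)
  path <- withr::local_tempfile(fileext = ".clstr")
  write_cluster_report(cl, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^>Cluster", lines)), 1L)
  expect_equal(sum(grepl("\\*$", lines)), 1L)
  expect_equal(length(lines), 3L)
})
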