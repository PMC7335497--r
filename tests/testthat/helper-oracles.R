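# Independent oracles used across the suite.  These deliberately do NOT
# share code with the package: the repeat miner is a literal enumeration
# over (start, unit size, count) triples, the aligner is a plain-R Gotoh
# DP, and Biostrings provides a third-party alignment engine for identity
# re-verification at scale.

rand_dna <- function(n, n_rate = 0) {
  alpha <- c("A", "C", "G", "T")
  chars <- sample(alpha, n, replace = TRUE)
  if (n_rate > 0) {
    hit <- runif(n) < n_rate
    chars[hit] <- "N"
  }
  paste(chars, collapse = "")
}

mutate_dna <- function(sequence, n_subs) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  pos <- sample(seq_along(chars), n_subs)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

make_tx <- function(sequences, source_tag = "eco1",
                    seq_id = paste0("t", seq_along(sequences))) {
  tibble::tibble(
    seq_id = seq_id, description = "", source_tag = source_tag,
    sequence = sequences, length = nchar(sequences)
  )
}

oracle_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        paste(rep(substr(motif, 1L, d), k / d), collapse = "") == motif) {
      return(FALSE)
    }
  }
  TRUE
}

# Literal brute force: every (start, unit size) is tried; copies are
# counted by direct substring comparison; a run is kept when it meets the
# threshold, is left-maximal (the preceding unit-length block differs from
# the motif), has a primitive motif, and does not overlap an already-kept
# run of the same unit size (leftmost precedence).  Equal-interval runs of
# different unit sizes keep the shortest period.
oracle_find_ssrs <- function(sequence, thresholds = mining_thresholds()) {
  n <- nchar(sequence)
  rows <- list()
  for (k in 1:6) {
    minr <- thresholds$min_repeats[k]
    kept_end <- 0L
    start <- 1L
    while (start + k * minr - 1L <= n) {
      motif <- substr(sequence, start, start + k - 1L)
      if (grepl("N", motif, fixed = TRUE)) { start <- start + 1L; next }
      copies <- 1L
      while (start + (copies + 1L) * k - 1L <= n &&
             substr(sequence, start + copies * k,
                    start + (copies + 1L) * k - 1L) == motif) {
        copies <- copies + 1L
      }
      ok <- copies >= minr
      if (ok && start - k >= 1L &&
          substr(sequence, start - k, start - 1L) == motif) {
        ok <- FALSE # not left-maximal
      }
      if (ok && !oracle_primitive(motif)) ok <- FALSE
      if (ok && start <= kept_end) ok <- FALSE # leftmost precedence
      if (ok) {
        end <- start + copies * k - 1L
        rows[[length(rows) + 1L]] <-
          data.frame(motif = motif, unit_size = k, repeat_count = copies,
                     start = start, end = end)
        kept_end <- end
      }
      start <- start + 1L
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(motif = character(), unit_size = integer(),
                      repeat_count = integer(), start = integer(),
                      end = integer()))
  }
  out <- out[order(out$start, out$end, out$unit_size), , drop = FALSE]
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  out <- out[order(out$start, out$unit_size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Plain-R Gotoh DP, score only.  Same scoring convention as the package
# (length-L gap costs open + (L-1) * ext); written independently.
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = -4, ext = -1, end_free = FALSE) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L) # gap in b
  Y <- matrix(NEG, n + 1L, m + 1L) # gap in a
  M[1L, 1L] <- 0
  for (i in seq_len(n)) {
    X[i + 1L, 1L] <- if (end_free) 0 else open + (i - 1L) * ext
  }
  for (j in seq_len(m)) {
    Y[1L, j + 1L] <- if (end_free) 0 else open + (j - 1L) * ext
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + open, X[i, j + 1L] + ext,
                               Y[i, j + 1L] + open)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + open, Y[i + 1L, j] + ext,
                               X[i + 1L, j] + open)
    }
  }
  if (end_free) {
    max(M[n + 1L, ], X[n + 1L, ], Y[n + 1L, ],
        M[, m + 1L], X[, m + 1L], Y[, m + 1L])
  } else {
    max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  }
}

# Third-party oracle: Biostrings with gapOpening = 3, gapExtension = 1,
# which prices a length-L gap at 3 + L = 4 + (L - 1), the package's
# convention.
bios_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

bios_global_score <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = bios_submat(),
                                      gapOpening = 3, gapExtension = 1)
  Biostrings::score(pa)
}

bios_overlap_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                      substitutionMatrix = bios_submat(),
                                      gapOpening = 3, gapExtension = 1)
  Biostrings::nmatch(pa) / min(nchar(a), nchar(b))
}

# Partition helpers: a partition is a sorted list of sorted member keys.
partition_of <- function(keys, groups) {
  parts <- split(keys, groups)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1L))])
}

family_partition <- function(transcripts) {
  keys <- paste(transcripts$source_tag, transcripts$seq_id, sep = "|")
  fam <- sub("_.*$", "", transcripts$seq_id)
  partition_of(keys, fam)
}

cluster_partition <- function(clusters) {
  keys <- paste(clusters$source_tag, clusters$seq_id, sep = "|")
  partition_of(keys, clusters$cluster_id)
}

# Literal re-implementation of the paralogy rule sentence: a cluster is
# removed when it contains a sequence with multiple same-motif loci while
# another sequence has fewer loci of that motif.
oracle_false_positive <- function(count_matrix) {
  # rows = members, cols = motifs, entries = locus counts
  for (j in seq_len(ncol(count_matrix))) {
    cnt <- count_matrix[, j]
    if (any(cnt >= 2L) && any(cnt < max(cnt))) return(TRUE)
  }
  FALSE
}
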