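# Synthetic multi-ecotype transcript families with planted repeat
# polymorphisms and decoys, plus a truth table, so every pipeline stage is
# testable without downloading real transcriptome assemblies.
#
# Each family has one random backbone; ecotype copies differ by the
# planted repeat-tract length, by substitutions at the configured rate
# (never inside a repeat tract or its anchor flanks, so planted truth
# stays exact), and optionally by orientation (a fraction of copies is
# emitted reverse-complemented).  Guard bases at both tract boundaries
# prevent the flanking backbone from extending a planted repeat by a
# whole unit, which would silently shift the planted count.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Study conditions for the synthetic dataset: two ecotypes by default,
#' transcript lengths typical of assembled transcripts (400-800 bp), 30%
#' of families carrying a planted cross-ecotype repeat-count polymorphism,
#' the five decoy categories at 10% each, 1% cross-ecotype substitution
#' divergence and 20% negative-strand copies.  The remaining families are
#' plain background transcripts without a planted repeat.
#'
#' @param n_families Number of transcript families.
#' @param n_ecotypes Number of samples/ecotypes (>= 2).
#' @param length_range Transcript length range in bp.
#' @param polymorphic_fraction Fraction of families with a planted
#'   cross-ecotype repeat-count difference.
#' @param decoy_rates Named fractions for the decoy categories
#'   `mononucleotide` (polymorphic single-base run, removed by the
#'   mononucleotide filter), `near_end` (polymorphic repeat closer than
#'   `min_flank` to a sequence end), `paralog` (one member carries two
#'   same-motif loci, another only one - the false-positive signature),
#'   `monomorphic` (equal counts everywhere) and `within_file` (two
#'   isoforms of one ecotype differ, no other ecotype has the locus).
#' @param repeat_count_range Named list mapping plantable unit size
#'   ("2".."4") to the (min, max) repeat count drawn for the base allele.
#' @param mono_count_range Count range for planted mononucleotide runs.
#' @param substitution_rate Per-base substitution rate applied to
#'   non-reference ecotype copies outside repeat tracts and anchors.
#' @param negative_strand_rate Fraction of emitted copies that are
#'   reverse-complemented.
#' @param min_flank Flank length the truth table treats as detectable
#'   (mirrors [enrichment_params()]).
#' @param thresholds [mining_thresholds()] the truth table mirrors.
#' @param rng_seed Integer seed; the dataset is fully deterministic given
#'   the seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_families = 100L,
                              n_ecotypes = 2L,
                              length_range = c(400L, 800L),
                              polymorphic_fraction = 0.30,
                              decoy_rates = c(mononucleotide = 0.10,
                                              near_end = 0.10,
                                              paralog = 0.10,
                                              monomorphic = 0.10,
                                              within_file = 0.10),
                              repeat_count_range = list(`2` = c(6L, 13L),
                                                        `3` = c(5L, 10L),
                                                        `4` = c(5L, 8L)),
                              mono_count_range = c(10L, 16L),
                              substitution_rate = 0.01,
                              negative_strand_rate = 0.20,
                              min_flank = 50L,
                              thresholds = mining_thresholds(),
                              rng_seed = 1L) {
  n_families <- as.integer(n_families)
  n_ecotypes <- as.integer(n_ecotypes)
  if (is.na(n_families) || n_families < 1L) {
    stop("`n_families` must be >= 1", call. = FALSE)
  }
  if (is.na(n_ecotypes) || n_ecotypes < 2L) {
    stop("`n_ecotypes` must be >= 2", call. = FALSE)
  }
  needed <- c("mononucleotide", "near_end", "paralog", "monomorphic",
              "within_file")
  if (!all(needed %in% names(decoy_rates))) {
    stop("`decoy_rates` must name: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  fr <- c(polymorphic_fraction, unname(decoy_rates))
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-9) {
    stop("category fractions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  if (substitution_rate < 0 || substitution_rate > 1 ||
      negative_strand_rate < 0 || negative_strand_rate > 1) {
    stop("rates must lie in [0,1]", call. = FALSE)
  }
  longest_tract <- max(
    vapply(names(repeat_count_range), function(k) {
      as.integer(k) * (max(repeat_count_range[[k]]) + 3L)
    }, integer(1)),
    max(mono_count_range)
  )
  if (length_range[1L] <= 2L * min_flank + longest_tract + 20L) {
    stop("`length_range` minimum too small for the planted tracts and ",
         "flanks", call. = FALSE)
  }
  structure(
    list(n_families = n_families, n_ecotypes = n_ecotypes,
         length_range = as.integer(length_range),
         polymorphic_fraction = polymorphic_fraction,
         decoy_rates = decoy_rates,
         repeat_count_range = repeat_count_range,
         mono_count_range = as.integer(mono_count_range),
         substitution_rate = substitution_rate,
         negative_strand_rate = negative_strand_rate,
         min_flank = as.integer(min_flank),
         thresholds = thresholds,
         rng_seed = as.integer(rng_seed)),
    class = "simulation_config"
  )
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_primitive_motif <- function(k) {
  repeat {
    m <- rand_seq(k)
    if (is_primitive_motif(m)) return(m)
  }
}

# a fixed base different from `avoid`; deterministic so that every ecotype
# copy of a family receives the same guard and backbones stay comparable
guard_base <- function(avoid) {
  setdiff(c("A", "C", "G", "T"), avoid)[1L]
}

substitute_bases <- function(sequence, rate, protected) {
  if (rate <= 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  hit <- setdiff(hit, protected)
  for (p in hit) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Insert a guarded repeat tract into a backbone after position `p`
# (0 <= p <= nchar).  Returns list(sequence, start, end).
plant_tract <- function(backbone, p, motif, count) {
  k <- nchar(motif)
  tract <- strrep(motif, count)
  left <- substr(backbone, 1L, p)
  right <- substr(backbone, p + 1L, nchar(backbone))
  # guard bases so the backbone cannot extend the planted run
  last_unit_base <- substr(motif, k, k)
  first_unit_base <- substr(motif, 1L, 1L)
  if (nchar(left) > 0L) {
    substr(left, nchar(left), nchar(left)) <- guard_base(last_unit_base)
  }
  if (nchar(right) > 0L) {
    substr(right, 1L, 1L) <- guard_base(first_unit_base)
  }
  list(sequence = paste0(left, tract, right),
       start = p + 1L, end = p + count * k)
}

#' Generate a synthetic multi-ecotype dataset
#'
#' Builds transcript families shared across ecotypes with planted
#' polymorphic repeats and decoys, together with a truth table recording
#' every planted locus and whether the pipeline is expected to detect it
#' (`expected_detectable` re-derives the pipeline's own filters - unit
#' size >= 2, flanks >= `min_flank`, counts meeting the mining thresholds,
#' and a genuine cross-ecotype count difference - independently of the
#' pipeline code).  Fully deterministic given `config$rng_seed`.
#'
#' @param config A [simulation_config()] object.
#' @return A list with `transcripts` (tibble; `source_tag` is the ecotype
#'   label `eco1`, `eco2`, ...) and `truth` (tibble with one row per
#'   planted locus per emitted record: `family_id`, `category`, `locus`,
#'   `ecotype`, `seq_id`, `motif`, `canonical_motif`, `unit_size`,
#'   `repeat_count`, `left_flank`, `right_flank`, `strand`,
#'   `expected_detectable`).
#' @export
simulate_transcripts <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$rng_seed, {
    n_fam <- config$n_families
    cats <- c("polymorphic", "mononucleotide_decoy", "near_end_decoy",
              "paralog_decoy", "monomorphic", "within_file_decoy")
    fracs <- c(config$polymorphic_fraction,
               config$decoy_rates[["mononucleotide"]],
               config$decoy_rates[["near_end"]],
               config$decoy_rates[["paralog"]],
               config$decoy_rates[["monomorphic"]],
               config$decoy_rates[["within_file"]])
    n_cat <- floor(fracs * n_fam + 1e-9)
    fam_cat <- c(rep(cats, n_cat),
                 rep("background", n_fam - sum(n_cat)))
    ecotags <- paste0("eco", seq_len(config$n_ecotypes))
    min_thr <- config$thresholds$min_repeats

    tx_rows <- list()
    truth_rows <- list()
    for (fam in seq_len(n_fam)) {
      cat_f <- fam_cat[fam]
      L <- sample(seq.int(config$length_range[1L], config$length_range[2L]),
                  1L)
      backbone <- rand_seq(L)
      fam_id <- sprintf("fam%05d", fam)

      emit <- function(eco, seq_id, sequence, planted) {
        rc <- stats::runif(1L) < config$negative_strand_rate
        strand <- if (rc) "-" else "+"
        if (rc) sequence <- reverse_complement(sequence)
        tx_rows[[length(tx_rows) + 1L]] <<- tibble::tibble(
          seq_id = seq_id, description = "", source_tag = eco,
          sequence = sequence, length = nchar(sequence)
        )
        for (pl in planted) {
          truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
            family_id = fam_id, category = cat_f, locus = pl$locus,
            ecotype = eco, seq_id = seq_id, motif = pl$motif,
            canonical_motif = canonical_motif(pl$motif),
            unit_size = nchar(pl$motif), repeat_count = pl$count,
            left_flank = pl$start - 1L,
            right_flank = nchar(sequence) - pl$end,
            strand = strand
          )
        }
      }

      if (cat_f == "background") {
        for (eco in ecotags) {
          s <- if (eco == ecotags[1L]) backbone else {
            substitute_bases(backbone, config$substitution_rate, integer(0))
          }
          emit(eco, paste0(fam_id, "_", eco), s, list())
        }
        next
      }

      if (cat_f == "mononucleotide_decoy") {
        motif <- sample(c("A", "C", "G", "T"), 1L)
        counts <- sample(seq.int(config$mono_count_range[1L],
                                 config$mono_count_range[2L]),
                         config$n_ecotypes, replace = TRUE)
        if (length(unique(counts)) == 1L) counts[2L] <- counts[2L] + 2L
      } else if (cat_f == "within_file_decoy" ||
                 cat_f %in% c("polymorphic", "near_end_decoy",
                              "monomorphic", "paralog_decoy")) {
        k <- as.integer(sample(names(config$repeat_count_range), 1L))
        rng <- config$repeat_count_range[[as.character(k)]]
        motif <- rand_primitive_motif(k)
        base_count <- sample(seq.int(rng[1L], rng[2L]), 1L)
        counts <- if (cat_f == "monomorphic") {
          rep(base_count, config$n_ecotypes)
        } else {
          base_count + c(0L, sample(1:3, config$n_ecotypes - 1L,
                                    replace = TRUE))
        }
      }

      k <- nchar(motif)
      margin <- config$min_flank + 10L
      max_tract <- max(counts) * k
      pick_pos <- function(lo, hi) {
        if (hi < lo) {
          stop("infeasible simulation config: planted tract plus flanks ",
               "exceed the transcript length", call. = FALSE)
        }
        sample(seq.int(lo, hi), 1L)
      }
      p <- if (cat_f == "near_end_decoy") {
        pick_pos(5L, config$min_flank - 5L)
      } else if (cat_f == "paralog_decoy") {
        pick_pos(margin, L - margin - 2L * max_tract - 150L)
      } else {
        pick_pos(margin, L - margin - max_tract)
      }

      if (cat_f == "paralog_decoy") {
        # second same-motif locus, present only in the first ecotype
        p2 <- p + max_tract + 150L
        count2 <- max(counts[1L], min_thr[k])
        for (e in seq_along(ecotags)) {
          pl1 <- plant_tract(backbone, p, motif, counts[e])
          seq_e <- pl1$sequence
          planted <- list(list(locus = 1L, motif = motif,
                               count = counts[e], start = pl1$start,
                               end = pl1$end))
          if (e == 1L) {
            pl2 <- plant_tract(seq_e, p2 + (pl1$end - pl1$start + 1L),
                               motif, count2)
            seq_e <- pl2$sequence
            planted <- c(planted, list(list(locus = 2L, motif = motif,
                                            count = count2,
                                            start = pl2$start,
                                            end = pl2$end)))
          }
          if (e > 1L) {
            protected <- seq.int(max(1L, pl1$start - 30L),
                                 min(nchar(seq_e), pl1$end + 30L))
            seq_e <- substitute_bases(seq_e, config$substitution_rate,
                                      protected)
          }
          emit(ecotags[e], paste0(fam_id, "_", ecotags[e]), seq_e, planted)
        }
        next
      }

      if (cat_f == "within_file_decoy") {
        # two isoforms of ecotype 1 with differing counts; no other ecotype
        for (iso in 1:2) {
          pl <- plant_tract(backbone, p, motif, counts[iso])
          emit(ecotags[1L], paste0(fam_id, "_", ecotags[1L], "_iso", iso),
               pl$sequence,
               list(list(locus = 1L, motif = motif, count = counts[iso],
                         start = pl$start, end = pl$end)))
        }
        next
      }

      # polymorphic, monomorphic, mononucleotide, near-end families:
      # one copy per ecotype
      for (e in seq_along(ecotags)) {
        pl <- plant_tract(backbone, p, motif, counts[e])
        seq_e <- pl$sequence
        if (e > 1L) {
          protected <- seq.int(max(1L, pl$start - 30L),
                               min(nchar(seq_e), pl$end + 30L))
          seq_e <- substitute_bases(seq_e, config$substitution_rate,
                                    protected)
        }
        emit(ecotags[e], paste0(fam_id, "_", ecotags[e]), seq_e,
             list(list(locus = 1L, motif = motif, count = counts[e],
                       start = pl$start, end = pl$end)))
      }
    }

    transcripts <- dplyr::bind_rows(tx_rows)
    truth <- dplyr::bind_rows(truth_rows)
    if (nrow(truth) > 0L) {
      flag <- truth |>
        dplyr::group_by(.data$family_id, .data$locus) |>
        dplyr::summarise(
          expected_detectable =
            .data$category[1L] == "polymorphic" &&
            .data$unit_size[1L] >= 2L &&
            all(.data$left_flank >= config$min_flank) &&
            all(.data$right_flank >= config$min_flank) &&
            dplyr::n_distinct(.data$repeat_count) >= 2L &&
            all(.data$repeat_count >= min_thr[.data$unit_size[1L]]),
          .groups = "drop"
        )
      truth <- dplyr::left_join(truth, flag, by = c("family_id", "locus"))
    } else {
      truth <- tibble::tibble(
        family_id = character(), category = character(), locus = integer(),
        ecotype = character(), seq_id = character(), motif = character(),
        canonical_motif = character(), unit_size = integer(),
        repeat_count = integer(), left_flank = integer(),
        right_flank = integer(), strand = character(),
        expected_detectable = logical()
      )
    }
    list(transcripts = transcripts, truth = truth)
  })
}

#' Write a synthetic dataset to disk
#'
#' One FASTA file per ecotype plus a `truth.tsv` table, generated with
#' [simulate_transcripts()].  Byte-identical for a fixed seed.
#'
#' @param config A [simulation_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `fasta_paths` (named by ecotype) and
#'   `truth_path`.
#' @export
generate_dataset <- function(config = simulation_config(), out_dir) {
  sim <- simulate_transcripts(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ecos <- unique(sim$transcripts$source_tag)
  paths <- vapply(ecos, function(eco) {
    p <- file.path(out_dir, paste0(eco, ".fa"))
    write_transcripts(sim$transcripts[sim$transcripts$source_tag == eco, ],
                      p)
    p
  }, character(1))
  truth_path <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(sim$truth, truth_path)
  invisible(list(fasta_paths = paths, truth_path = truth_path))
}

#' Score pipeline candidates against the planted truth
#'
#' A candidate matches a planted locus when all its member sequences
#' belong to that locus's family, the motifs agree (canonical form, on
#' either strand), and the multiset of reported repeat counts equals the
#' planted one.  Precision is matched candidates over all candidates
#' (reported as 1 with `precision_defined = FALSE` when there are no
#' candidates); recall is matched detectable loci over all loci flagged
#' `expected_detectable`.
#'
#' @param candidates Candidate tibble from [enrich_candidates()] /
#'   [run_ssr_pipeline()].
#' @param truth Truth tibble from [simulate_transcripts()].
#' @return A list: `precision`, `recall`, `precision_defined`,
#'   `n_candidates`, `n_detectable`, `n_matched`, and `confusion` (tibble
#'   of truth categories with planted and detected locus counts).
#' @export
score_against_truth <- function(candidates, truth) {
  stopifnot(is.data.frame(candidates), is.data.frame(truth))
  if (nrow(truth) == 0L) stop("empty truth table", call. = FALSE)

  truth_groups <- truth |>
    dplyr::group_by(.data$family_id, .data$locus) |>
    dplyr::summarise(
      category = .data$category[1L],
      canonical_motif = .data$canonical_motif[1L],
      canonical_motif_rc = canonical_motif(
        reverse_complement(.data$motif[1L])),
      counts = paste(sort(.data$repeat_count), collapse = ","),
      seq_ids = list(.data$seq_id),
      expected_detectable = .data$expected_detectable[1L],
      .groups = "drop"
    )
  fam_of <- unique(truth[, c("seq_id", "family_id")])

  cand_ids <- unique(candidates$candidate_id)
  matched_cand <- logical(length(cand_ids))
  matched_truth <- logical(nrow(truth_groups))
  for (ci in seq_along(cand_ids)) {
    rows <- candidates[candidates$candidate_id == cand_ids[ci], ,
                       drop = FALSE]
    fams <- unique(fam_of$family_id[match(rows$seq_id, fam_of$seq_id)])
    if (length(fams) != 1L || anyNA(fams)) next
    cm <- rows$canonical_motif[1L]
    counts <- paste(sort(rows$repeat_count), collapse = ",")
    hit <- which(
      truth_groups$family_id == fams &
        (truth_groups$canonical_motif == cm |
           truth_groups$canonical_motif_rc == cm) &
        truth_groups$counts == counts & !matched_truth
    )
    if (length(hit) > 0L) {
      matched_cand[ci] <- TRUE
      matched_truth[hit[1L]] <- TRUE
    }
  }

  n_cand <- length(cand_ids)
  n_detectable <- sum(truth_groups$expected_detectable)
  n_matched_detectable <- sum(matched_truth & truth_groups$expected_detectable)
  confusion <- truth_groups |>
    dplyr::mutate(detected = matched_truth) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_planted = dplyr::n(),
                     n_detected = sum(.data$detected), .groups = "drop")
  list(
    precision = if (n_cand == 0L) 1 else sum(matched_cand) / n_cand,
    precision_defined = n_cand > 0L,
    recall = if (n_detectable == 0L) NA_real_ else
      n_matched_detectable / n_detectable,
    n_candidates = n_cand,
    n_detectable = n_detectable,
    n_matched = n_matched_detectable,
    confusion = confusion
  )
}
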