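#' Read a multi-FASTA transcript file
#'
#' Reads assembled transcripts and tags every record with the sample
#' (ecotype) it came from.  Sequences are normalised: lowercase bases are
#' uppercased, `U` is mapped to `T`, and any remaining character outside
#' A/C/G/T/N (e.g. IUPAC ambiguity codes) is replaced by `N` with a
#' warning.  Gzip-compressed files (`.gz`) are handled transparently.
#'
#' @param path Path to a FASTA file.
#' @param source_tag Label for the sample the file represents; defaults to
#'   the file name without extension.  Must be non-empty.
#' @return A tibble with one row per record, in file order, and columns
#'   `seq_id` (first whitespace-delimited token of the header),
#'   `description` (rest of the header, `""` when absent), `source_tag`,
#'   `sequence` and `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 sample transcript", "ACGTACGT"), fa)
#' read_transcripts(fa, source_tag = "eco1")
#' @export
read_transcripts <- function(path, source_tag = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  if (is.null(source_tag)) {
    source_tag <- sub("\\.gz$", "", basename(path))
    source_tag <- sub("\\.[^.]*$", "", source_tag)
  }
  if (!is.character(source_tag) || length(source_tag) != 1L ||
      is.na(source_tag) || !nzchar(source_tag)) {
    stop("`source_tag` must be a non-empty string", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("empty input: no FASTA records in ", path, call. = FALSE)
  }
  headers <- names(set)
  seq_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(seq_id)) {
    dup <- seq_id[duplicated(seq_id)][1L]
    stop("duplicate record id in ", path, ": ", dup, call. = FALSE)
  }
  seqs <- unname(toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  n_bad <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  if (n_bad > 0L) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    warning(n_bad, " non-ACGTN character(s) replaced by N in ", path,
            call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("zero-length sequence in ", path, call. = FALSE)
  }
  tibble::tibble(
    seq_id = unname(seq_id),
    description = unname(description),
    source_tag = source_tag,
    sequence = seqs,
    length = nchar(seqs)
  )
}

#' Write transcripts to a FASTA file
#'
#' Writes standard multi-FASTA with sequence lines wrapped at 60 columns;
#' the header is `seq_id description` (the description is omitted when
#' empty).  `read_transcripts(write_transcripts(x))` preserves id,
#' description and sequence.
#'
#' @param transcripts Tibble as returned by [read_transcripts()]; columns
#'   `seq_id` and `sequence` are required, `description` is optional.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  stopifnot(is.data.frame(transcripts))
  if (nrow(transcripts) == 0L) {
    stop("no records to write", call. = FALSE)
  }
  desc <- if ("description" %in% names(transcripts)) {
    transcripts$description
  } else {
    rep("", nrow(transcripts))
  }
  desc[is.na(desc)] <- ""
  headers <- ifelse(nzchar(desc),
                    paste(transcripts$seq_id, desc),
                    transcripts$seq_id)
  set <- Biostrings::BStringSet(transcripts$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read transcripts from several sample files
#'
#' Convenience wrapper over [read_transcripts()]: reads each file with its
#' own source tag and row-binds the results.  `(source_tag, seq_id)` must
#' be unique across the combined set.
#'
#' @param paths Character vector of FASTA paths (one per sample/ecotype).
#' @param source_tags Optional character vector of labels, one per path.
#' @return A single tibble of transcripts.
#' @export
read_transcript_set <- function(paths, source_tags = NULL) {
  if (length(paths) < 1L) stop("no input files", call. = FALSE)
  if (is.null(source_tags)) source_tags <- vector("list", length(paths))
  if (length(source_tags) != length(paths)) {
    stop("`source_tags` must match `paths` in length", call. = FALSE)
  }
  out <- purrr::map2(paths, source_tags,
                     function(p, tag) read_transcripts(p, source_tag = tag))
  tags <- vapply(out, function(x) x$source_tag[1L], character(1))
  if (anyDuplicated(tags)) {
    stop("duplicate source tags across input files: ",
         paste(unique(tags[duplicated(tags)]), collapse = ", "),
         call. = FALSE)
  }
  dplyr::bind_rows(out)
}
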