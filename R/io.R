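# File formats: paired FASTQ (Phred+33, plain or gzip), FASTA, mothur-dialect
# count tables, mask TSVs and the per-position provenance sidecar. Sequence
# parsing goes through Biostrings; tabular formats through readr.

#' Read paired-end FASTQ files into a pair table
#'
#' Records must appear in the same order in both files with matching IDs (up
#' to `/1`,`/2` or ` 1:`,` 2:` suffixes). Qualities are decoded as Phred+33.
#'
#' @param fwd_path,rev_path Paths to the R1 and R2 FASTQ files (may be
#'   gzipped).
#' @return A tibble with columns `id`, `fwd_seq`, `fwd_qual` (list of integer
#'   vectors), `rev_seq`, `rev_qual`.
#' @export
read_paired_fastq <- function(fwd_path, rev_path) {
  fwd <- read_fastq_one(fwd_path)
  rev <- read_fastq_one(rev_path)
  if (nrow(fwd) != nrow(rev)) {
    n <- min(nrow(fwd), nrow(rev)) + 1L
    first <- if (nrow(fwd) > nrow(rev)) fwd$id[n] else rev$id[n]
    abort(sprintf(
      "record count mismatch: %d forward vs %d reverse records (first unpaired record: %s)",
      nrow(fwd), nrow(rev), first))
  }
  fid <- strip_pair_suffix(fwd$id)
  rid <- strip_pair_suffix(rev$id)
  bad <- which(fid != rid)
  if (length(bad))
    abort(sprintf("read ID mismatch at record %d: '%s' vs '%s'",
                  bad[1], fwd$id[bad[1]], rev$id[bad[1]]))
  tibble(id = fid,
         fwd_seq = fwd$seq, fwd_qual = phred_decode(fwd$qual),
         rev_seq = rev$seq, rev_qual = phred_decode(rev$qual))
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  validate_fastq(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e)
      abort(sprintf("malformed FASTQ in %s: %s", path, conditionMessage(e))))
  tibble(id = sub("\\s.*$", "", names(x)),
         seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

# Structural pass over the 4-line records so malformed input fails with the
# offending line number (Biostrings' parser pads short quality lines
# silently, so this runs before parsing, not as an error fallback).
validate_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "@"))
      abort(sprintf("malformed FASTQ in %s at line %d: expected '@' header",
                    path, i))
    if (i + 3L > length(lines))
      abort(sprintf("malformed FASTQ in %s: truncated record starting at line %d",
                    path, i))
    if (!startsWith(lines[i + 2L], "+"))
      abort(sprintf("malformed FASTQ in %s at line %d: expected '+' separator",
                    path, i + 2L))
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L]))
      abort(sprintf("malformed FASTQ in %s at line %d: sequence/quality length mismatch",
                    path, i + 3L))
    i <- i + 4L
  }
  invisible(TRUE)
}

strip_pair_suffix <- function(ids) sub("/[12]$", "", ids)

#' Write a FASTQ file (Phred+33)
#'
#' @param ids,seqs Character vectors of record IDs and sequences.
#' @param quals List of integer Phred vectors, one per record.
#' @param path Output path.
#' @param suffix Optional ID suffix (e.g. `"/1"`).
#' @export
write_fastq <- function(ids, seqs, quals, path, suffix = "") {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste0(ids, suffix)
  q <- Biostrings::BStringSet(phred_encode(quals))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read or write a FASTA file
#'
#' @param path File path.
#' @return `read_fasta` returns a tibble with `id` and `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(id = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences (names become record IDs).
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read or write an abundance count table (mothur dialect)
#'
#' Two tab-separated columns with header
#' `Representative_Sequence<TAB>total`.
#'
#' @param x A tibble with columns `id` and `abundance`.
#' @param path File path.
#' @export
write_count_table <- function(x, path) {
  out <- tibble(Representative_Sequence = x$id, total = x$abundance)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("Representative_Sequence", "total") %in% names(x)))
    abort("count table must have columns Representative_Sequence and total")
  tibble(id = as.character(x$Representative_Sequence),
         abundance = as.integer(x$total))
}

#' Read or write per-sequence error masks
#'
#' Tab-separated: sequence ID and a comma-separated list of 0-based masked
#' positions (empty string for an empty mask).
#'
#' @param masks A tibble with columns `id` and `mask` (list of logical
#'   vectors) or `positions` (list of 0-based integer vectors).
#' @param path File path.
#' @export
write_masks <- function(masks, path) {
  pos <- if ("positions" %in% names(masks)) masks$positions
         else lapply(masks$mask, function(m) which(m) - 1L)
  out <- tibble(id = masks$id,
                positions = vapply(pos, paste, character(1), collapse = ","))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_masks
#' @param seq_len Length of the sequences the masks apply to (to rebuild
#'   logical vectors); if `NULL` only the position lists are returned.
#' @export
read_masks <- function(path, seq_len = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  pos <- lapply(x$positions, function(s) {
    if (is.na(s) || s == "") integer(0)
    else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  })
  out <- tibble(id = x$id, positions = pos)
  if (!is.null(seq_len)) {
    out$mask <- lapply(pos, function(p) {
      m <- logical(seq_len)
      m[p + 1L] <- TRUE
      m
    })
  }
  out
}
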