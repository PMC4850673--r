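# Paired-end read merging. The reverse read is reverse-complemented and the
# ungapped offset maximizing the number of matching overlap bases is chosen
# (ties prefer the larger overlap). Outside the overlap the covering read
# supplies base and quality; inside it, agreeing bases keep the higher
# quality, an ambiguous base defers to the other read, and conflicting calls
# go to the higher-quality read only when the Phred difference reaches
# `q_delta` (otherwise N with quality 0, which marks the contig for culling).

#' Merge paired-end reads into contigs with per-position provenance
#'
#' @param pairs A pair table from [read_paired_fastq()] or
#'   [simulate_mock()]`$pairs` (columns `id`, `fwd_seq`, `fwd_qual`,
#'   `rev_seq`, `rev_qual`; the reverse read in sequencing orientation).
#' @param min_overlap Minimum overlap length in bases; pairs for which no
#'   ungapped offset reaches it are culled (counted, not fatal).
#' @param q_delta Minimum Phred difference for a conflicting overlap position
#'   to be resolved toward the higher-quality read.
#' @return A contig tibble with columns `id`, `seq`, `length`, `n_conflict`,
#'   `n_unknown`, `has_n`, plus provenance columns `fwd_start`, `rev_start`
#'   (0-based contig coordinates), `fwd_seq`, `rev_seq` (reverse-complemented)
#'   and `fwd_qual`, `rev_qual` (reverse-read qualities in reverse-complement
#'   orientation). The number and IDs of culled pairs are attached as
#'   attribute `"rejected"`.
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, q_delta = 6L) {
  check_scalar_int(min_overlap, "min_overlap", min = 1)
  check_scalar_int(q_delta, "q_delta", min = 0)
  stopifnot(all(c("id", "fwd_seq", "fwd_qual", "rev_seq", "rev_qual") %in%
                  names(pairs)))
  n <- nrow(pairs)
  rev_rc <- revcomp(pairs$rev_seq)
  out <- vector("list", n)
  rejected <- logical(n)
  for (i in seq_len(n)) {
    ct <- merge_one(pairs$fwd_seq[i], pairs$fwd_qual[[i]],
                    rev_rc[i], rev(pairs$rev_qual[[i]]),
                    min_overlap, q_delta)
    if (is.null(ct)) rejected[i] <- TRUE else out[[i]] <- ct
  }
  out <- out[!rejected]
  grab <- function(fld, how) vapply(out, `[[`, how, fld)
  contigs <- tibble(
    id = pairs$id[!rejected],
    seq = grab("seq", character(1)),
    length = grab("length", integer(1)),
    n_conflict = grab("n_conflict", integer(1)),
    n_unknown = grab("n_unknown", integer(1)),
    has_n = grab("has_n", logical(1)),
    fwd_start = grab("fwd_start", integer(1)),
    rev_start = grab("rev_start", integer(1)),
    fwd_seq = pairs$fwd_seq[!rejected],
    rev_seq = rev_rc[!rejected],
    fwd_qual = pairs$fwd_qual[!rejected],
    rev_qual = lapply(pairs$rev_qual[!rejected], rev))
  attr(contigs, "rejected") <- pairs$id[rejected]
  if (any(rejected))
    inform(sprintf("%d pair(s) culled: no ungapped offset reached min_overlap = %d",
                   sum(rejected), min_overlap))
  contigs
}

merge_one <- function(fwd, fq, rev_rc, rq, min_overlap, q_delta) {
  lf <- nchar(fwd); lr <- nchar(rev_rc)
  if (min_overlap > min(lf, lr)) return(NULL)
  off <- best_offset_cpp(fwd, rev_rc, min_overlap)
  if (off$overlap < 0) return(NULL)
  o <- off$offset
  start <- min(0L, o)
  L <- max(lf, o + lr) - start
  fwd_start <- -start
  rev_start <- o - start

  Fb <- rep(NA_character_, L); Fq <- rep(NA_integer_, L)
  Rb <- rep(NA_character_, L); Rq <- rep(NA_integer_, L)
  Fb[fwd_start + seq_len(lf)] <- seq_chars(fwd)
  Fq[fwd_start + seq_len(lf)] <- fq
  Rb[rev_start + seq_len(lr)] <- seq_chars(rev_rc)
  Rq[rev_start + seq_len(lr)] <- rq

  seq <- ifelse(is.na(Fb), Rb, Fb)
  both <- !is.na(Fb) & !is.na(Rb)
  nf <- both & Fb == "N"; nr <- both & Rb == "N"
  match_ <- both & !nf & !nr & Fb == Rb
  unknown <- both & (nf | nr)
  conflict <- both & !nf & !nr & Fb != Rb

  seq[match_] <- Fb[match_]
  seq[nf & !nr] <- Rb[nf & !nr]
  seq[nr & !nf] <- Fb[nr & !nf]
  seq[nf & nr] <- "N"
  if (any(conflict)) {
    dq <- Fq - Rq
    f_wins <- conflict & dq >= q_delta
    r_wins <- conflict & -dq >= q_delta
    tie <- conflict & !f_wins & !r_wins
    seq[f_wins] <- Fb[f_wins]
    seq[r_wins] <- Rb[r_wins]
    seq[tie] <- "N"
  }
  list(seq = paste(seq, collapse = ""), length = L,
       n_conflict = as.integer(sum(conflict)),
       n_unknown = as.integer(sum(unknown)),
       has_n = any(seq == "N"),
       fwd_start = fwd_start, rev_start = rev_start)
}

#' Per-position overlap status of merged contigs
#'
#' Recovers, for every contig position, which reads cover it and whether the
#' two base calls agree: `NOT_OVERLAP` (one read only), `MATCH`, `CONFLICT`
#' (two differing non-ambiguous calls) or `UNKNOWN` (at least one ambiguous
#' call).
#'
#' @param contigs A contig tibble from [merge_pairs()].
#' @return A tibble with `contig_id`, `pos` (0-based) and `overlap` (factor).
#' @export
overlap_status <- function(contigs) {
  rows <- pmap(contigs[, c("id", "length", "fwd_start", "rev_start",
                           "fwd_seq", "rev_seq")],
    function(id, length, fwd_start, rev_start, fwd_seq, rev_seq) {
      tibble(contig_id = id, pos = 0:(length - 1L),
             overlap = overlap_codes(length, fwd_start, rev_start,
                                     fwd_seq, rev_seq))
    })
  out <- list_rbind(rows)
  out$overlap <- factor(OVERLAP_LEVELS[out$overlap], levels = OVERLAP_LEVELS)
  out
}

# integer codes 1..4 indexing OVERLAP_LEVELS, vector over contig positions
overlap_codes <- function(L, fwd_start, rev_start, fwd_seq, rev_seq) {
  lf <- nchar(fwd_seq); lr <- nchar(rev_seq)
  Fb <- rep(NA_character_, L); Rb <- rep(NA_character_, L)
  Fb[fwd_start + seq_len(lf)] <- seq_chars(fwd_seq)
  Rb[rev_start + seq_len(lr)] <- seq_chars(rev_seq)
  code <- rep(1L, L)
  both <- !is.na(Fb) & !is.na(Rb)
  amb <- both & (Fb == "N" | Rb == "N")
  code[both & !amb & Fb == Rb] <- 2L
  code[both & !amb & Fb != Rb] <- 3L
  code[amb] <- 4L
  code
}

#' Write contigs and their provenance sidecar
#'
#' `write_contigs` writes a FASTA of the consensus sequences;
#' `write_provenance` writes a tab-separated sidecar with one row per contig
#' position (contig_id, pos, fwd_pos, fwd_base, fwd_qual, rev_pos, rev_base,
#' rev_qual, overlap; absent read coordinates are empty).
#'
#' @param contigs A contig tibble from [merge_pairs()].
#' @param path Output path.
#' @export
write_contigs <- function(contigs, path) {
  write_fasta(setNames(contigs$seq, contigs$id), path)
}

#' @rdname write_contigs
#' @export
write_provenance <- function(contigs, path) {
  ov <- overlap_status(contigs)
  rows <- pmap(contigs[, c("id", "length", "fwd_start", "rev_start",
                           "fwd_seq", "rev_seq", "fwd_qual", "rev_qual")],
    function(id, length, fwd_start, rev_start, fwd_seq, rev_seq,
             fwd_qual, rev_qual) {
      lf <- nchar(fwd_seq); lr <- nchar(rev_seq)
      pos <- 0:(length - 1L)
      fp <- pos - fwd_start; fp[fp < 0 | fp >= lf] <- NA_integer_
      rp <- pos - rev_start; rp[rp < 0 | rp >= lr] <- NA_integer_
      tibble(contig_id = id, pos = pos,
             fwd_pos = fp,
             fwd_base = ifelse(is.na(fp), NA, substring(fwd_seq, fp + 1, fp + 1)),
             fwd_qual = ifelse(is.na(fp), NA_integer_, fwd_qual[fp + 1]),
             rev_pos = rp,
             rev_base = ifelse(is.na(rp), NA, substring(rev_seq, rp + 1, rp + 1)),
             rev_qual = ifelse(is.na(rp), NA_integer_, rev_qual[rp + 1]))
    })
  out <- list_rbind(rows)
  out$overlap <- ov$overlap
  readr::write_tsv(out, path, na = "")
  invisible(path)
}
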