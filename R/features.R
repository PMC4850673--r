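# Per-position features for the error classifier. The selected 6-feature set
# (retained after correlation-based feature selection) is: forward-read
# position, homopolymer status and Phred quality; reverse-read position and
# Phred quality; and the overlap status between the two reads. The full
# 17-feature set adds, per read, the GGC-motif flag and the homopolymer
# status and quality of the neighbouring positions. Read coordinates are
# 0-based; -1 is the sentinel for "read absent" (and for neighbours beyond
# the read ends).

#' Homopolymer status of a position within a sequence
#'
#' Returns -1 when the base is ambiguous (`N`), 0 when the maximal run
#' containing the position is a singleton, and otherwise the 1-based index of
#' the position within its homopolymer run (runs of length >= 2).
#'
#' @param seq A nucleotide string.
#' @param i 1-based position in `seq`.
#' @examples
#' homopolymer_status("ACGT", 3)   # 0
#' homopolymer_status("GAAAT", 3)  # 2 (second base of the AAA run)
#' @export
homopolymer_status <- function(seq, i) {
  check_scalar_int(i, "i", min = 1)
  if (i > nchar(seq)) abort("index out of range")
  homopolymer_vec(seq)[i]
}

homopolymer_vec <- function(seq) {
  ch <- seq_chars(seq)
  r <- rle(ch)
  runlen <- rep(r$lengths, r$lengths)
  posin <- sequence(r$lengths)
  out <- ifelse(runlen >= 2L, posin, 0L)
  out[ch == "N"] <- -1L
  as.integer(out)
}

#' Is a position immediately preceded by a GGC motif?
#'
#' True iff the three bases immediately before position `i` spell `GGC`
#' (the motif associated with quality drops and miscalls on Illumina
#' instruments).
#'
#' @param seq A nucleotide string.
#' @param i 1-based position in `seq`.
#' @examples
#' ggc_before("AGGCT", 5)  # TRUE
#' ggc_before("AGGCT", 4)  # FALSE
#' @export
ggc_before <- function(seq, i) {
  check_scalar_int(i, "i", min = 1)
  if (i > nchar(seq)) abort("index out of range")
  i >= 4L && substr(seq, i - 3L, i - 1L) == "GGC"
}

ggc_vec <- function(seq) {
  L <- nchar(seq)
  out <- logical(L)
  if (L >= 4L) {
    starts <- gregexpr("GGC", seq, fixed = TRUE)[[1]]
    if (starts[1] != -1L) {
      at <- starts + 3L
      out[at[at <= L]] <- TRUE
    }
  }
  out
}

#' Extract per-position classifier features from merged contigs
#'
#' @param contigs A contig tibble from [merge_pairs()] (provenance columns
#'   required).
#' @param mode `"selected"` for the 6 retained features, `"full"` for all 17
#'   candidates.
#' @return A tibble with one row per contig position in contig order:
#'   `contig_id`, `pos` (0-based contig coordinate) and the feature columns.
#'   Numeric features use sentinel -1 where the read does not cover the
#'   position; `overlap` is a factor over
#'   NOT_OVERLAP/MATCH/CONFLICT/UNKNOWN.
#' @export
extract_features <- function(contigs, mode = c("selected", "full")) {
  mode <- match.arg(mode)
  prov <- c("length", "fwd_start", "rev_start", "fwd_seq", "rev_seq",
            "fwd_qual", "rev_qual")
  if (!all(prov %in% names(contigs)))
    abort("contig provenance missing: run merge_pairs() with provenance enabled")
  if (nrow(contigs) == 0) abort("empty contig table")
  acc <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    acc[[i]] <- feature_cols_one(
      contigs$id[i], contigs$length[i], contigs$fwd_start[i],
      contigs$rev_start[i], contigs$fwd_seq[i], contigs$rev_seq[i],
      contigs$fwd_qual[[i]], contigs$rev_qual[[i]], mode)
  }
  cols <- names(acc[[1]])
  out <- tibble(!!!lapply(setNames(cols, cols),
                          function(cn) unlist(lapply(acc, `[[`, cn),
                                              use.names = FALSE)))
  out$overlap <- factor(OVERLAP_LEVELS[out$overlap], levels = OVERLAP_LEVELS)
  out
}

feature_cols_one <- function(id, L, fwd_start, rev_start, fwd_seq, rev_seq,
                             fq, rq, mode) {
  lf <- nchar(fwd_seq); lr <- nchar(rev_seq)
  pos <- 0:(L - 1L)
  fp <- pos - fwd_start; fcov <- fp >= 0L & fp < lf
  rp <- pos - rev_start; rcov <- rp >= 0L & rp < lr

  pick <- function(v, p, cov) {
    # v indexed 1-based by read position p (0-based); -1 where not covered
    idx <- ifelse(cov & p >= 0L & p < length(v), p + 1L, NA_integer_)
    out <- rep(-1L, length(p))
    ok <- !is.na(idx)
    out[ok] <- as.integer(v[idx[ok]])
    out
  }

  hpf <- homopolymer_vec(fwd_seq)
  hpr <- homopolymer_vec(rev_seq)
  ov <- overlap_codes(L, fwd_start, rev_start, fwd_seq, rev_seq)

  cols <- list(
    contig_id = rep(id, L),
    pos = pos,
    fwd_pos = ifelse(fcov, fp, -1L),
    fwd_homopolymer = pick(hpf, fp, fcov),
    fwd_qual = pick(fq, fp, fcov),
    rev_pos = ifelse(rcov, rp, -1L),
    rev_qual = pick(rq, rp, rcov),
    overlap = ov
  )
  if (mode == "full") {
    ggf <- ggc_vec(fwd_seq); ggr <- ggc_vec(rev_seq)
    cols <- c(cols, list(
      fwd_ggc_before = pick(ggf, fp, fcov),
      fwd_prev_homopolymer = pick(hpf, fp - 1L, fcov),
      fwd_prev_qual = pick(fq, fp - 1L, fcov),
      fwd_next_homopolymer = pick(hpf, fp + 1L, fcov),
      fwd_next_qual = pick(fq, fp + 1L, fcov),
      rev_homopolymer = pick(hpr, rp, rcov),
      rev_ggc_before = pick(ggr, rp, rcov),
      rev_prev_homopolymer = pick(hpr, rp - 1L, rcov),
      rev_prev_qual = pick(rq, rp - 1L, rcov),
      rev_next_homopolymer = pick(hpr, rp + 1L, rcov),
      rev_next_qual = pick(rq, rp + 1L, rcov)
    ))
    ord <- c("contig_id", "pos", "fwd_pos", "fwd_homopolymer", "fwd_qual",
             "fwd_ggc_before", "fwd_prev_homopolymer", "fwd_prev_qual",
             "fwd_next_homopolymer", "fwd_next_qual",
             "rev_pos", "rev_homopolymer", "rev_qual", "rev_ggc_before",
             "rev_prev_homopolymer", "rev_prev_qual",
             "rev_next_homopolymer", "rev_next_qual", "overlap")
    cols <- cols[ord]
  }
  cols
}

#' Write a feature matrix as tab-separated text
#'
#' @param features A tibble from [extract_features()], optionally with a
#'   `label` column.
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if ("overlap" %in% names(x))
    x$overlap <- factor(x$overlap, levels = OVERLAP_LEVELS)
  if ("label" %in% names(x))
    x$label <- factor(x$label, levels = c("ERROR", "CORRECT"))
  as_tibble(x)
}
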