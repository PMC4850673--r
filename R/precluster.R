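# Abundance-sorted single-linkage preclustering with masked distances: a
# rare sequence differing from a more abundant representative by at most
# `diffs` unmasked positions is merged into it and its abundance added.
# Masked (predicted-erroneous) positions on either sequence never increase
# the distance. With all-empty masks this reproduces the plain Pre-cluster
# baseline. After clustering the representative sequences are emitted
# unchanged (masking never mutates sequence content).

#' Masked Hamming distance between two equal-length sequences
#'
#' Counts positions where the sequences differ, excluding positions masked in
#' either sequence; gap characters (`-`) count as differences against bases
#' and never against other gaps.
#'
#' @param seq_a,seq_b Equal-length sequence strings.
#' @param mask_a,mask_b Logical vectors the same length as the sequences
#'   (`NULL` for no mask).
#' @return A non-negative integer.
#' @examples
#' masked_distance("ACGT", "AGGT")                    # 1
#' masked_distance("ACGT", "AGGT", c(FALSE, TRUE, FALSE, FALSE))  # 0
#' @export
masked_distance <- function(seq_a, seq_b, mask_a = NULL, mask_b = NULL) {
  L <- nchar(seq_a)
  if (nchar(seq_b) != L) abort("sequences must be equal length")
  mask_a <- mask_a %||% logical(L)
  mask_b <- mask_b %||% logical(L)
  if (length(mask_a) != L || length(mask_b) != L)
    abort("masks must match the sequence length")
  diff <- charToRaw(seq_a) != charToRaw(seq_b)
  sum(diff & !mask_a & !mask_b)
}

#' Allowed differences for preclustering at a given sequence length
#'
#' The "1 difference per 100 nt" rule: `max(1, floor(len / 100))` computed on
#' the ungapped length, so 250 nt allows 2 differences and 430 nt allows 4.
#'
#' @param seq_len Ungapped sequence length (>= 1).
#' @export
allowed_diffs <- function(seq_len) {
  stopifnot(all(seq_len >= 1))
  pmax(1L, as.integer(seq_len %/% 100L))
}

#' Single-linkage preclustering of unique sequences with masked distances
#'
#' Sequences are processed in abundance-descending order (ties broken
#' lexicographically by sequence). Each sequence is compared against every
#' strictly-more-abundant current representative; if any lies within `diffs`
#' masked differences it is merged into the nearest one (ties: highest
#' current abundance, then earliest), its abundance added immediately so that
#' later sequences see post-merge abundances.
#'
#' @param uniques A unique-sequence table from [dereplicate()] (columns `id`,
#'   `seq`, `abundance`, optional `mask` and `member_ids`). All sequences
#'   must have equal length.
#' @param diffs Maximum allowed masked distance, or `"auto"` for
#'   [allowed_diffs()] on the ungapped length.
#' @return An `iped_precluster` object: list with `table` (the merged
#'   unique-sequence table, original sequences, updated abundances, unioned
#'   member IDs), `merge_map` (tibble `id`, `representative_id`, `distance`,
#'   `merged`) and counts. [tidy()] returns the merge map, [glance()] a
#'   one-row summary.
#' @export
precluster <- function(uniques, diffs = "auto") {
  stopifnot(all(c("id", "seq", "abundance") %in% names(uniques)))
  n <- nrow(uniques)
  if (n == 0) abort("empty unique-sequence table")
  L <- unique(nchar(uniques$seq))
  if (length(L) != 1)
    abort("sequences must be equal length; align them to the same region first")
  if (!"mask" %in% names(uniques)) uniques$mask <- lapply(rep(L, n), logical)
  if (!"member_ids" %in% names(uniques))
    uniques$member_ids <- as.list(uniques$id)

  ung_len <- nchar(gsub("-", "", uniques$seq, fixed = TRUE))
  diffs_vec <- if (identical(diffs, "auto")) allowed_diffs(ung_len)
               else rep(check_scalar_int(diffs, "diffs", min = 0), n)

  ord <- order(-uniques$abundance, uniques$seq)
  x <- uniques[ord, ]
  dv <- diffs_vec[ord]
  maskmat <- matrix(unlist(x$mask, use.names = FALSE), nrow = n, byrow = TRUE)
  res <- precluster_cpp(x$seq, maskmat, as.numeric(x$abundance),
                        as.integer(dv))
  target <- res$target

  merge_map <- tibble(id = x$id,
                      representative_id = x$id[target],
                      distance = ifelse(res$dist < 0, NA_integer_, res$dist),
                      merged = target != seq_len(n))
  reps <- which(!merge_map$merged)
  members <- split(seq_len(n), target)
  table <- x[reps, ]
  table$abundance <- vapply(as.character(reps),
                            function(r) sum(x$abundance[members[[r]]]),
                            numeric(1))
  table$abundance <- as.integer(table$abundance)
  table$member_ids <- lapply(as.character(reps), function(r)
    unlist(x$member_ids[members[[r]]], use.names = FALSE))
  table <- arrange(table, desc(.data$abundance), .data$seq)

  structure(list(table = table, merge_map = merge_map,
                 n_input = n, n_merged = sum(merge_map$merged),
                 diffs = if (identical(diffs, "auto")) "auto" else diffs),
            class = "iped_precluster")
}

#' Emit the denoised unique-sequence table after mask reversion
#'
#' Representative sequences are byte-identical to their original input
#' sequences (masking is a transient flag and never mutates sequence
#' content); abundances are the merged totals and member IDs the unions.
#'
#' @param result An [precluster()] result.
#' @return The denoised unique-sequence tibble (`id`, `seq`, `abundance`,
#'   `member_ids`).
#' @export
revert_and_emit <- function(result) {
  stopifnot(inherits(result, "iped_precluster"))
  result$table[, c("id", "seq", "abundance", "member_ids")]
}

#' @export
print.iped_precluster <- function(x, ...) {
  cat(sprintf("<iped_precluster> %d unique sequences -> %d representatives (%d merges)\n",
              x$n_input, nrow(x$table), x$n_merged))
  invisible(x)
}

#' @export
tidy.iped_precluster <- function(x, ...) x$merge_map

#' @export
glance.iped_precluster <- function(x, ...) {
  tibble(n_input = x$n_input, n_representatives = nrow(x$table),
         n_merged = x$n_merged,
         total_abundance = sum(x$table$abundance))
}

#' Write a denoised table and its merge map
#'
#' Emits `<prefix>.fasta`, `<prefix>.count_table` and `<prefix>.map` (a
#' mothur-.map-like TSV: rare ID, representative ID, masked distance).
#'
#' @param result An [precluster()] result.
#' @param prefix Output path prefix.
#' @export
write_precluster <- function(result, prefix) {
  tab <- revert_and_emit(result)
  write_fasta(setNames(tab$seq, tab$id), paste0(prefix, ".fasta"))
  write_count_table(tab, paste0(prefix, ".count_table"))
  mm <- result$merge_map[result$merge_map$merged, ]
  readr::write_tsv(tibble(rare_id = mm$id,
                          representative_id = mm$representative_id,
                          distance = mm$distance),
                   paste0(prefix, ".map"))
  invisible(prefix)
}
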