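# Dereplication: collapse identical contig sequences into unique sequences
# with abundances. Contigs containing an ambiguous base are culled first,
# mirroring the make.contigs-style removal of ambiguous contigs.

#' Dereplicate contigs into a unique-sequence table
#'
#' @param contigs A contig tibble (needs columns `id` and `seq`); contigs
#'   containing `N` are removed first and counted.
#' @return A tibble of unique sequences with columns `id` (representative =
#'   first member), `seq`, `abundance`, `member_ids` (list) and `mask`
#'   (all-false logical vectors, to be filled by the classifier), sorted by
#'   abundance descending with ties broken lexicographically by sequence.
#'   The number of culled contigs is attached as attribute `"n_culled"`.
#' @examples
#' ctg <- tibble::tibble(id = c("a", "b", "c"),
#'                       seq = c("ACGT", "ACGT", "AGGT"))
#' dereplicate(ctg)
#' @export
dereplicate <- function(contigs) {
  stopifnot(all(c("id", "seq") %in% names(contigs)))
  if (nrow(contigs) == 0) abort("empty contig table")
  keep <- !str_detect(contigs$seq, "N")
  n_culled <- sum(!keep)
  x <- contigs[keep, c("id", "seq")]
  if (nrow(x) == 0) {
    warn(sprintf("no contigs left after culling %d ambiguous contig(s)", n_culled))
    out <- tibble(id = character(), seq = character(), abundance = integer(),
                  member_ids = list(), mask = list())
    attr(out, "n_culled") <- n_culled
    return(out)
  }
  out <- x |>
    summarise(abundance = dplyr::n(), member_ids = list(.data$id),
              id = .data$id[1], .by = "seq") |>
    arrange(desc(.data$abundance), .data$seq)
  out$mask <- lapply(nchar(out$seq), logical)
  out <- out[, c("id", "seq", "abundance", "member_ids", "mask")]
  attr(out, "n_culled") <- n_culled
  out
}
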