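# Training labels: each contig position is ERROR or CORRECT according to a
# global affine-gap alignment against the best-matching reference sequence.
# Substitutions and inserted contig bases are labeled at their own position;
# a reference deletion labels the contig position immediately left of the
# gap. Contigs below `min_identity` to every reference are skipped.

#' Label contig positions as erroneous or correct against references
#'
#' @param contigs A contig tibble (columns `id`, `seq`). Contigs containing
#'   `N` are excluded (they are culled from the pipeline anyway).
#' @param refs Reference sequences (tibble `id`/`seq`, named character vector
#'   or `DNAStringSet`).
#' @param min_identity Minimum identity to the best reference for a contig to
#'   be labeled; lower-identity contigs are skipped with a count.
#' @return A tibble with `contig_id`, `pos` (0-based) and `label` (factor
#'   ERROR/CORRECT), in contig order. Per-contig alignment summaries are
#'   attached as attribute `"alignments"`, and the IDs of skipped contigs as
#'   attribute `"skipped"`.
#' @export
label_by_reference <- function(contigs, refs, min_identity = 0.9) {
  stopifnot(all(c("id", "seq") %in% names(contigs)))
  refs <- as_ref_tibble(refs)
  if (nrow(refs) == 0) abort("empty reference set")
  stopifnot(min_identity > 0, min_identity <= 1)
  keep <- !str_detect(contigs$seq, "N")
  x <- contigs[keep, ]
  if (nrow(x) == 0) abort("no unambiguous contigs to label")
  al <- align_to_refs(x$seq, refs)
  al$contig_id <- x$id
  ok <- al$identity >= min_identity
  skipped <- c(contigs$id[!keep], x$id[!ok])
  if (any(!ok))
    inform(sprintf("%d contig(s) below min_identity = %g skipped",
                   sum(!ok), min_identity))
  x <- x[ok, ]
  alk <- al[ok, ]
  rows <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    L <- nchar(x$seq[i])
    err <- logical(L)
    err[unique(alk$err_qpos[[i]]) + 1L] <- TRUE
    rows[[i]] <- tibble(contig_id = x$id[i], pos = 0:(L - 1L), error = err)
  }
  out <- list_rbind(rows)
  out$label <- factor(ifelse(out$error, "ERROR", "CORRECT"),
                      levels = c("ERROR", "CORRECT"))
  out$error <- NULL
  attr(out, "alignments") <-
    alk[, c("contig_id", "ref_id", "identity", "subs", "ins", "del")]
  attr(out, "skipped") <- skipped
  out
}
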