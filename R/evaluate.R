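# seq.error-style evaluation: the error rate of a sequence table is the
# ratio of the number of deletions, insertions and substitutions over the
# total number of bases, abundance-weighted, with each sequence counted
# against its best-matching reference under an affine-gap global alignment.

#' Error rate of a sequence table against reference sequences
#'
#' @param seqs A tibble with columns `seq` and `abundance` (and optionally
#'   `id`), e.g. from [dereplicate()] or [revert_and_emit()].
#' @param refs Reference sequences (tibble `id`/`seq`, named character
#'   vector or `DNAStringSet`).
#' @return An `iped_error_report`: list with `per_seq` (per-sequence counts),
#'   `total_errors`, `total_bases` and `error_rate`. [glance()] returns the
#'   aggregate row, [tidy()] the per-sequence table.
#' @export
error_rate <- function(seqs, refs) {
  stopifnot(all(c("seq", "abundance") %in% names(seqs)))
  if (nrow(seqs) == 0) abort("empty sequence table")
  refs <- as_ref_tibble(refs)
  if (nrow(refs) == 0) abort("empty reference set")
  al <- align_to_refs(seqs$seq, refs)
  per <- tibble(
    id = if ("id" %in% names(seqs)) seqs$id else as.character(seq_len(nrow(seqs))),
    abundance = as.integer(seqs$abundance),
    ref_id = al$ref_id,
    subs = al$subs, ins = al$ins, del = al$del,
    bases = nchar(seqs$seq),
    err_rpos = al$err_rpos)
  total_errors <- sum(per$abundance * (per$subs + per$ins + per$del))
  total_bases <- sum(per$abundance * per$bases)
  structure(list(per_seq = per, total_errors = total_errors,
                 total_bases = total_bases,
                 error_rate = total_errors / total_bases),
            class = "iped_error_report")
}

#' @export
print.iped_error_report <- function(x, ...) {
  cat(sprintf("<iped_error_report> %d unique sequences, %d errors / %d bases = %.6f\n",
              nrow(x$per_seq), x$total_errors, x$total_bases, x$error_rate))
  invisible(x)
}

#' @export
glance.iped_error_report <- function(x, ...) {
  tibble(n_unique = nrow(x$per_seq), total_errors = x$total_errors,
         total_bases = x$total_bases, error_rate = x$error_rate)
}

#' @export
tidy.iped_error_report <- function(x, ...) {
  x$per_seq[, c("id", "abundance", "ref_id", "subs", "ins", "del", "bases")]
}

#' Per-position error rate along the amplicon
#'
#' Errors are attributed to reference-anchored amplicon coordinates (the
#' coordinate of the mismatched or deleted reference base; insertions go to
#' the preceding coordinate).
#'
#' @inheritParams error_rate
#' @return A tibble with `pos` (0-based amplicon coordinate), the
#'   abundance-weighted `errors` count, `coverage` and `rate`, of class
#'   `iped_position_error` (plottable with [ggplot2::autoplot()]).
#' @export
positionwise_error <- function(seqs, refs) {
  refs <- as_ref_tibble(refs)
  L <- unique(nchar(refs$seq))
  if (length(L) != 1)
    abort("references must cover one amplicon region of equal length")
  rep_ <- error_rate(seqs, refs)
  counts <- numeric(L)
  for (i in seq_len(nrow(rep_$per_seq))) {
    rp <- rep_$per_seq$err_rpos[[i]]
    if (length(rp)) {
      tab <- table(rp)
      counts[as.integer(names(tab)) + 1L] <-
        counts[as.integer(names(tab)) + 1L] +
        as.integer(tab) * rep_$per_seq$abundance[i]
    }
  }
  coverage <- sum(rep_$per_seq$abundance)
  structure(tibble(pos = 0:(L - 1L), errors = counts,
                   coverage = coverage, rate = counts / coverage),
            class = c("iped_position_error", class(tibble())))
}

#' @export
autoplot.iped_position_error <- function(object, ...) {
  ggplot(object, aes(x = .data$pos, y = .data$rate)) +
    geom_line(colour = "firebrick") +
    labs(x = "Amplicon position", y = "Error rate") +
    theme_minimal()
}

#' Compare raw, Pre-cluster and masked (IPED-style) denoising on a simulation
#'
#' Runs merge -> dereplicate -> {nothing | plain preclustering | predicted
#' masks + masked preclustering} -> [error_rate()] and reports the three
#' rates with their relative reductions. When the simulation carries truth
#' records, an oracle row (true per-position errors used as masks) bounds
#' the achievable performance.
#'
#' @param sim An [simulate_mock()] result.
#' @param model A trained [train_ensemble()] model (required for the masked
#'   pipeline).
#' @param threshold Mask confidence threshold.
#' @param diffs Preclustering difference allowance (`"auto"` = 1 per 100 nt).
#' @param min_overlap,q_delta Merge parameters.
#' @param include_oracle Add the truth-mask bound when truth is available.
#' @param seed Seed (kept for reproducibility bookkeeping; all stages here
#'   are deterministic given the inputs and model).
#' @return An `iped_comparison`: list with `table` (one row per pipeline:
#'   error_rate, errors, bases, n_uniques, reduction_vs_raw) and stage
#'   counts. [tidy()] returns the table.
#' @export
compare_pipelines <- function(sim, model, threshold = 0.5, diffs = "auto",
                              min_overlap = 10L, q_delta = 6L,
                              include_oracle = TRUE, seed = NULL) {
  stopifnot(inherits(sim, "iped_sim"))
  if (missing(model) || is.null(model)) abort("a trained model is required")
  if (!is.null(seed)) set.seed(seed)
  contigs <- merge_pairs(sim$pairs, min_overlap = min_overlap,
                         q_delta = q_delta)
  n_rejected <- length(attr(contigs, "rejected"))
  uniques <- dereplicate(contigs)
  n_culled <- attr(uniques, "n_culled")

  # screen to the dominant contig length (rare mis-offset merges would
  # otherwise mix lengths, which preclustering rejects)
  lens <- nchar(uniques$seq)
  modal <- as.integer(names(sort(table(rep(lens, uniques$abundance)),
                                 decreasing = TRUE))[1])
  n_offlength <- sum(uniques$abundance[lens != modal])
  uniques <- uniques[lens == modal, ]

  clean <- filter(contigs, !.data$has_n, .data$length == modal)

  raw <- error_rate(uniques, sim$refs)

  base_pc <- precluster(uniques, diffs = diffs)   # all-false masks
  base_rate <- error_rate(revert_and_emit(base_pc), sim$refs)

  feats <- extract_features(clean, mode = "selected")
  masks <- predict_mask(model, feats, threshold = threshold)
  masked_uniques <- aggregate_masks(uniques, masks)
  iped_pc <- precluster(masked_uniques, diffs = diffs)
  iped_rate <- error_rate(revert_and_emit(iped_pc), sim$refs)

  rows <- list(
    tibble(pipeline = "raw", error_rate = raw$error_rate,
           errors = raw$total_errors, bases = raw$total_bases,
           n_uniques = nrow(uniques)),
    tibble(pipeline = "precluster", error_rate = base_rate$error_rate,
           errors = base_rate$total_errors, bases = base_rate$total_bases,
           n_uniques = nrow(revert_and_emit(base_pc))),
    tibble(pipeline = "iped", error_rate = iped_rate$error_rate,
           errors = iped_rate$total_errors, bases = iped_rate$total_bases,
           n_uniques = nrow(revert_and_emit(iped_pc))))

  if (include_oracle && nrow(sim$truth) >= 0 && nrow(sim$refs) > 0) {
    oracle_uniques <- oracle_masks(uniques, sim)
    oracle_pc <- precluster(oracle_uniques, diffs = diffs)
    oracle_rate <- error_rate(revert_and_emit(oracle_pc), sim$refs)
    rows <- c(rows, list(
      tibble(pipeline = "iped_oracle", error_rate = oracle_rate$error_rate,
             errors = oracle_rate$total_errors,
             bases = oracle_rate$total_bases,
             n_uniques = nrow(revert_and_emit(oracle_pc)))))
  }
  table <- list_rbind(rows)
  raw_rate <- rows[[1]]$error_rate
  table$reduction_vs_raw <- if (raw_rate == 0) NA_real_ else
    100 * (1 - table$error_rate / raw_rate)

  structure(list(table = table,
                 counts = tibble(n_pairs = nrow(sim$pairs),
                                 n_rejected = n_rejected,
                                 n_ambiguous = n_culled,
                                 n_offlength = n_offlength,
                                 contig_length = modal)),
            class = "iped_comparison")
}

# True error masks at the unique-sequence level: a position is masked iff
# the representative sequence disagrees with the true amplicon of any of its
# member reads' source references (majority over members, ties masked).
oracle_masks <- function(uniques, sim) {
  ref_of <- setNames(sim$pairs$ref_id, sim$pairs$id)
  amp <- setNames(sim$refs$seq, sim$refs$id)
  uniques$mask <- lapply(seq_len(nrow(uniques)), function(i) {
    s <- uniques$seq[i]
    members <- uniques$member_ids[[i]]
    votes <- matrix(FALSE, length(members), nchar(s))
    for (k in seq_along(members)) {
      a <- amp[[ref_of[[members[k]]]]]
      if (nchar(a) == nchar(s))
        votes[k, ] <- charToRaw(s) != charToRaw(a)
    }
    2 * colSums(votes) >= nrow(votes)
  })
  uniques
}

#' @export
print.iped_comparison <- function(x, ...) {
  cat("<iped_comparison>\n")
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.iped_comparison <- function(x, ...) x$table

#' @export
glance.iped_comparison <- function(x, ...) {
  wide <- setNames(x$table$error_rate, x$table$pipeline)
  as_tibble(as.list(wide))
}

#' @export
autoplot.iped_comparison <- function(object, ...) {
  tab <- object$table
  tab$pipeline <- factor(tab$pipeline, levels = tab$pipeline)
  ggplot(tab, aes(x = .data$pipeline, y = .data$error_rate)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "Error rate") +
    theme_minimal()
}
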