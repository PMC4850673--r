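# End-to-end workflow: simulate (or read) paired reads, merge, label a
# training subsample against the references, train the ensemble, predict
# masks, run the baseline and masked preclustering, and report error rates.
# Every run directory is self-describing: the effective configuration is
# written alongside the outputs and stage logs, and re-running from it
# reproduces the outputs for the same seeds.

#' Build a pipeline configuration
#'
#' @param out_dir Run directory (created if needed).
#' @param fwd,rev Paths to paired FASTQ files; `NULL` to simulate instead.
#' @param refs Path to a reference FASTA, or `NULL` to synthesize references
#'   (only allowed when simulating).
#' @param preset Simulation preset (see [profile_preset()]).
#' @param n_pairs Number of simulated pairs.
#' @param n_refs Number of synthetic references.
#' @param train_pairs Number of pairs simulated for the training run.
#' @param min_overlap,q_delta Merge parameters.
#' @param ratio_a Learning-set error:non-error ratio.
#' @param threshold Mask confidence threshold.
#' @param diffs Preclustering difference allowance (`"auto"` = 1 per 100 nt).
#' @param model_dir Optional directory with a pre-trained model
#'   ([write_ensemble()]); skips the labeling/training stages.
#' @param seed Master seed; stage seeds are derived from it.
#' @param resume Skip stages whose outputs already exist.
#' @return An `iped_config` list.
#' @export
run_config <- function(out_dir, fwd = NULL, rev = NULL, refs = NULL,
                       preset = "v34", n_pairs = 20000L, n_refs = 15L,
                       train_pairs = 8000L, min_overlap = 10L, q_delta = 6L,
                       ratio_a = "1:3", threshold = 0.5, diffs = "auto",
                       model_dir = NULL, seed = 1L, resume = FALSE) {
  structure(list(out_dir = out_dir, fwd = fwd, rev = rev, refs = refs,
                 preset = preset, n_pairs = as.integer(n_pairs),
                 n_refs = as.integer(n_refs),
                 train_pairs = as.integer(train_pairs),
                 min_overlap = as.integer(min_overlap),
                 q_delta = as.integer(q_delta), ratio_a = ratio_a,
                 threshold = threshold, diffs = diffs,
                 model_dir = model_dir, seed = as.integer(seed),
                 resume = isTRUE(resume)),
            class = "iped_config")
}

#' @rdname run_config
#' @param path YAML file written by a previous run.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

# small deterministic seed derivation (kept below 2^31)
derive_seed <- function(seed, k) (seed * 7L + k * 1009L) %% 2147483647L

#' Run the full denoising workflow
#'
#' Stages: simulate (unless FASTQ inputs are given), merge, train (label a
#' training simulation against the references and fit the ensemble, unless a
#' model is supplied), predict masks, denoise (baseline and masked
#' preclustering) and error-rate comparison. Stage-level counts are logged
#' to stderr and `log.txt`; all tabular outputs are TSV.
#'
#' @param config An [run_config()] (or a path to its YAML serialization).
#' @return The run directory, invisibly; the comparison table is written to
#'   `comparison.tsv` and returned as attribute `"comparison"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "iped_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "log.txt")
  say <- function(...) {
    msg <- sprintf(...)
    inform(msg)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", sep = "", file = logf,
        append = TRUE)
  }
  cfg_list <- unclass(config)
  yaml::write_yaml(cfg_list, file.path(config$out_dir, "config.yaml"))

  simulate_input <- is.null(config$fwd)
  if (!simulate_input && is.null(config$refs))
    abort("no references: supply `refs` or enable simulation")

  done <- function(...) config$resume && all(file.exists(file.path(config$out_dir, c(...))))

  # --- stage: input ---------------------------------------------------------
  if (simulate_input) {
    prof <- profile_preset(config$preset)
    refs <- if (is.null(config$refs)) {
      set.seed(derive_seed(config$seed, 1L))
      synth_references(n = config$n_refs, length = prof$amplicon_len)
    } else read_fasta(config$refs)
    sim <- simulate_mock(refs, config$n_pairs, prof,
                         seed = derive_seed(config$seed, 2L))
    write_simulation(sim, file.path(config$out_dir, "sim"))
    pairs <- sim$pairs
    say("simulate: %d pairs from %d references", nrow(pairs), nrow(refs))
  } else {
    pairs <- read_paired_fastq(config$fwd, config$rev)
    refs <- read_fasta(config$refs)
    sim <- NULL
    say("input: %d pairs read", nrow(pairs))
  }

  # --- stage: merge ---------------------------------------------------------
  contigs <- merge_pairs(pairs, min_overlap = config$min_overlap,
                         q_delta = config$q_delta)
  write_contigs(contigs, file.path(config$out_dir, "contigs.fasta"))
  say("merge: %d contigs, %d pair(s) culled", nrow(contigs),
      length(attr(contigs, "rejected")))
  uniques <- dereplicate(contigs)
  say("dereplicate: %d uniques, %d ambiguous contig(s) culled",
      nrow(uniques), attr(uniques, "n_culled"))
  write_fasta(setNames(uniques$seq, uniques$id),
              file.path(config$out_dir, "uniques.fasta"))
  write_count_table(uniques, file.path(config$out_dir, "uniques.count_table"))

  # --- stage: train ---------------------------------------------------------
  if (!is.null(config$model_dir)) {
    model <- read_ensemble(config$model_dir)
    say("train: loaded model from %s", config$model_dir)
  } else {
    if (simulate_input) {
      train_sim <- simulate_mock(refs, config$train_pairs, prof,
                                 seed = derive_seed(config$seed, 3L))
      train_pairs <- train_sim$pairs
    } else {
      n <- min(config$train_pairs, nrow(pairs))
      set.seed(derive_seed(config$seed, 3L))
      train_pairs <- pairs[sample.int(nrow(pairs), n), ]
    }
    model <- train_from_pairs(train_pairs, refs,
                              min_overlap = config$min_overlap,
                              q_delta = config$q_delta,
                              ratio_a = config$ratio_a,
                              seed = derive_seed(config$seed, 4L))
    write_ensemble(model, file.path(config$out_dir, "model"))
    say("train: ensemble fitted on %d instances", model$n_train)
  }

  # --- stage: predict -------------------------------------------------------
  modal <- as.integer(names(sort(table(nchar(uniques$seq)),
                                 decreasing = TRUE))[1])
  uniques <- uniques[nchar(uniques$seq) == modal, ]
  clean <- filter(contigs, !.data$has_n, .data$length == modal)
  feats <- extract_features(clean, mode = "selected")
  masks <- predict_mask(model, feats, threshold = config$threshold)
  uniques <- aggregate_masks(uniques, masks)
  write_masks(tibble(id = uniques$id, mask = uniques$mask),
              file.path(config$out_dir, "masks.tsv"))
  say("predict: %d of %d positions masked", sum(masks$masked), nrow(masks))

  # --- stage: denoise -------------------------------------------------------
  baseline <- precluster(mutate(uniques, mask = lapply(nchar(.data$seq), logical)),
                         diffs = config$diffs)
  write_precluster(baseline, file.path(config$out_dir, "precluster"))
  denoised <- precluster(uniques, diffs = config$diffs)
  write_precluster(denoised, file.path(config$out_dir, "iped"))
  say("denoise: baseline %d -> %d, masked %d -> %d uniques",
      baseline$n_input, nrow(baseline$table),
      denoised$n_input, nrow(denoised$table))

  # --- stage: evaluate ------------------------------------------------------
  rates <- list(
    raw = error_rate(uniques, refs),
    precluster = error_rate(revert_and_emit(baseline), refs),
    iped = error_rate(revert_and_emit(denoised), refs))
  tab <- list_rbind(imap(rates, function(r, nm)
    tibble(pipeline = nm, error_rate = r$error_rate,
           errors = r$total_errors, bases = r$total_bases)))
  raw_rate <- tab$error_rate[tab$pipeline == "raw"]
  tab$reduction_vs_raw <- if (raw_rate == 0) NA_real_ else
    100 * (1 - tab$error_rate / raw_rate)
  readr::write_tsv(tab, file.path(config$out_dir, "comparison.tsv"))
  say("evaluate: raw %.2e, precluster %.2e, iped %.2e",
      tab$error_rate[1], tab$error_rate[2], tab$error_rate[3])

  out <- config$out_dir
  attr(out, "comparison") <- tab
  invisible(out)
}

#' Label a pair sample against references and train the ensemble
#'
#' Convenience wrapper: merge the pairs, label the resulting contigs by
#' reference alignment, extract selected-mode features and fit the
#' plurality-voting ensemble on a 1:3-balanced learning subset.
#'
#' @param pairs A pair table.
#' @param refs Reference sequences.
#' @param min_overlap,q_delta Merge parameters.
#' @param ratio_a Learning-set class ratio.
#' @param seed Integer seed.
#' @param min_identity Labeling identity threshold.
#' @return An `iped_ensemble` with the training bundle attached as attribute
#'   `"bundle"`.
#' @export
train_from_pairs <- function(pairs, refs, min_overlap = 10L, q_delta = 6L,
                             ratio_a = "1:3", seed = NULL,
                             min_identity = 0.9) {
  contigs <- merge_pairs(pairs, min_overlap = min_overlap, q_delta = q_delta)
  contigs <- filter(contigs, !.data$has_n)
  labels <- label_by_reference(contigs, refs, min_identity = min_identity)
  feats <- extract_features(
    contigs[contigs$id %in% unique(labels$contig_id), ], mode = "selected")
  inst <- inner_join(feats, labels, by = c("contig_id", "pos"))
  bundle <- build_training_bundle(inst, ratio_a = ratio_a, seed = seed)
  model <- train_ensemble(bundle, seed = seed)
  attr(model, "bundle") <- bundle
  model
}
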