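# Training-data assembly: dereplication of identical (features, label) rows,
# seeded shuffling, a stratified a/b/c split preserving the original class
# ratio, then rebalancing of the learning set to a fixed error:non-error
# ratio (1:3, capped at 5,000 erroneous / 15,000 non-erroneous instances)
# and of the validation set to 1:1. Plus correlation-based feature selection
# (CFS merit under cross-validation).

#' Build a learning/validation/test bundle from labeled instances
#'
#' @param instances A feature tibble (e.g. from [extract_features()] joined
#'   with [label_by_reference()]) with a `label` column (ERROR/CORRECT).
#'   Columns `contig_id` and `pos` are dropped before training.
#' @param ratio_a Error:non-error ratio for the learning subset, as a string
#'   `"1:3"`.
#' @param split Fractions for subsets a (learning), b (validation) and c
#'   (test); must sum to 1.
#' @param cap_error,cap_correct Caps on the learning-subset class sizes.
#' @param seed Integer seed for shuffling and downsampling.
#' @return An `iped_bundle`: list of tibbles `a`, `b`, `c` plus metadata.
#' @export
build_training_bundle <- function(instances, ratio_a = "1:3",
                                  split = c(a = 0.6, b = 0.2, c = 0.2),
                                  cap_error = 5000L, cap_correct = 15000L,
                                  seed = NULL) {
  if (!"label" %in% names(instances)) abort("instances must carry a `label` column")
  stopifnot(abs(sum(split) - 1) < 1e-8, length(split) == 3)
  x <- as_tibble(instances)
  x$label <- factor(as.character(x$label), levels = c("ERROR", "CORRECT"))
  if (any(is.na(x$label))) abort("labels must be ERROR or CORRECT")
  if (nlevels(droplevels(x$label)) < 2)
    abort("both classes must be present in the training instances")
  x <- x[, setdiff(names(x), c("contig_id", "pos"))]
  x <- distinct(x)                      # training-time dereplication
  if (!is.null(seed)) set.seed(seed)
  x <- x[sample.int(nrow(x)), ]

  ratio <- as.integer(strsplit(ratio_a, ":", fixed = TRUE)[[1]])
  if (length(ratio) != 2 || any(is.na(ratio)) || any(ratio < 1))
    abort("`ratio_a` must look like \"1:3\"")

  # stratified split preserving the class ratio
  part <- integer(nrow(x))
  for (cl in levels(x$label)) {
    idx <- which(x$label == cl)
    n <- length(idx)
    sizes <- floor(split * n)
    sizes[1] <- n - sum(sizes[-1])
    part[idx] <- rep(1:3, times = sizes)
  }
  a <- x[part == 1, ]; b <- x[part == 2, ]; cc <- x[part == 3, ]

  # learning subset: downsample to ratio_a, capped
  nE <- sum(a$label == "ERROR"); nC <- sum(a$label == "CORRECT")
  n_err <- min(nE, (nC * ratio[1]) %/% ratio[2], cap_error,
               (cap_correct * ratio[1]) %/% ratio[2])
  n_corr <- (n_err * ratio[2]) %/% ratio[1]
  if (n_err < cap_error)
    warn(sprintf("learning subset holds %d erroneous instances (cap %d)",
                 n_err, cap_error))
  a <- bind_rows(head(a[a$label == "ERROR", ], n_err),
                 head(a[a$label == "CORRECT", ], n_corr))
  a <- a[sample.int(nrow(a)), ]

  # validation subset: equal class counts
  nb <- min(sum(b$label == "ERROR"), sum(b$label == "CORRECT"))
  b <- bind_rows(head(b[b$label == "ERROR", ], nb),
                 head(b[b$label == "CORRECT", ], nb))
  b <- b[sample.int(nrow(b)), ]

  structure(list(a = a, b = b, c = cc, ratio_a = ratio_a,
                 split = split, seed = seed),
            class = "iped_bundle")
}

#' @export
print.iped_bundle <- function(x, ...) {
  f <- function(s) sprintf("%d (%d ERROR : %d CORRECT)", nrow(s),
                           sum(s$label == "ERROR"), sum(s$label == "CORRECT"))
  cat("<iped_bundle>\n  learning  a:", f(x$a),
      "\n  validation b:", f(x$b), "\n  test       c:", f(x$c), "\n")
  invisible(x)
}

#' @export
glance.iped_bundle <- function(x, ...) {
  tibble(n_a = nrow(x$a), n_b = nrow(x$b), n_c = nrow(x$c),
         a_error = sum(x$a$label == "ERROR"),
         a_correct = sum(x$a$label == "CORRECT"),
         ratio_a = x$ratio_a)
}

#' Correlation-based feature selection under cross-validation
#'
#' Greedy forward search maximizing the CFS merit
#' `k * mean(r_cf) / sqrt(k + k * (k - 1) * mean(r_ff))` where `r_cf` are
#' absolute feature-class correlations and `r_ff` absolute feature-feature
#' correlations, run independently per fold; features selected in a majority
#' of folds are returned. Constant features get correlation 0.
#'
#' @param instances Labeled feature tibble (as for
#'   [build_training_bundle()]).
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return Character vector of selected feature names (dummy-encoded factor
#'   features are reported under their original column name).
#' @export
select_features <- function(instances, folds = 3L, seed = NULL) {
  check_scalar_int(folds, "folds", min = 2)
  if (!"label" %in% names(instances)) abort("instances must carry a `label` column")
  enc <- make_encoder(instances)
  X <- encode_features(instances, enc, standardize = FALSE)
  y <- as.numeric(as_error_logical(instances$label))
  if (ncol(X) < 2) abort("need at least two features")
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = nrow(X)))
  chosen <- lapply(seq_len(folds), function(f) {
    cfs_forward(X[fold == f, , drop = FALSE], y[fold == f])
  })
  tab <- table(unlist(chosen))
  sel <- names(tab)[tab > folds / 2]
  unique(enc$origin[sel])
}

cfs_forward <- function(X, y) {
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    abs(cor(a, b))
  }
  p <- ncol(X)
  rcf <- vapply(seq_len(p), function(j) safe_cor(X[, j], y), numeric(1))
  # shrink class correlations indistinguishable from sampling noise to 0:
  # the raw merit of k uncorrelated noise features grows like sqrt(k), so
  # without a floor the forward search would absorb pure noise
  rcf[rcf < 2 / sqrt(nrow(X))] <- 0
  rff <- matrix(0, p, p)
  for (j in seq_len(p)) for (k in seq_len(p)) {
    if (k > j) rff[j, k] <- rff[k, j] <- safe_cor(X[, j], X[, k])
  }
  merit <- function(S) {
    k <- length(S)
    rbar_cf <- mean(rcf[S])
    rbar_ff <- if (k > 1) mean(rff[S, S][upper.tri(diag(k))]) else 0
    k * rbar_cf / sqrt(k + k * (k - 1) * rbar_ff)
  }
  sel <- integer(0)
  best <- -Inf
  repeat {
    cand <- setdiff(seq_len(p), sel)
    if (!length(cand)) break
    m <- vapply(cand, function(j) merit(c(sel, j)), numeric(1))
    if (max(m) <= best) break
    best <- max(m)
    sel <- c(sel, cand[which.max(m)])
  }
  colnames(X)[sel]
}
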