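# The plurality-voting ensemble: a multilayer perceptron (one hidden layer
# of 6 sigmoid units, softmax output, batch gradient descent with learning
# rate 0.3 and momentum 0.2 on standardized inputs) and a random forest of
# unpruned probability trees. Each member outputs per-class confidences in
# [0,1] summing to 1; the predicted class is the class of the highest
# confidence among all members' outputs, with exact ties resolved to CORRECT
# (conservative: do not mask).

# --- numeric encoding ------------------------------------------------------

# Encoder: which columns are numeric features, which factor levels become
# dummies, and (after train) standardization statistics.
make_encoder <- function(features) {
  drop <- c("contig_id", "pos", "label")
  cols <- setdiff(names(features), drop)
  numeric_cols <- cols[vapply(features[cols], is.numeric, logical(1))]
  factor_cols <- setdiff(cols, numeric_cols)
  dummies <- list()
  for (fc in factor_cols) {
    lev <- levels(factor(features[[fc]]))
    if (fc == "overlap") lev <- OVERLAP_LEVELS
    dummies[[fc]] <- lev[-1]            # first level is the baseline
  }
  out_names <- c(numeric_cols,
                 unlist(lapply(names(dummies), function(fc)
                   paste0(fc, "_", dummies[[fc]])), use.names = FALSE))
  origin <- c(setNames(numeric_cols, numeric_cols),
              unlist(lapply(names(dummies), function(fc)
                setNames(rep(fc, length(dummies[[fc]])),
                         paste0(fc, "_", dummies[[fc]])))))
  list(numeric = numeric_cols, dummies = dummies, names = out_names,
       origin = origin, center = NULL, scale = NULL)
}

encode_features <- function(features, enc, standardize = TRUE) {
  miss <- setdiff(c(enc$numeric, names(enc$dummies)), names(features))
  if (length(miss))
    abort(sprintf("feature columns missing (width mismatch with the model): %s",
                  paste(miss, collapse = ", ")))
  X <- matrix(0, nrow(features), length(enc$names),
              dimnames = list(NULL, enc$names))
  for (nc in enc$numeric) X[, nc] <- as.numeric(features[[nc]])
  for (fc in names(enc$dummies)) {
    v <- as.character(features[[fc]])
    for (lev in enc$dummies[[fc]])
      X[, paste0(fc, "_", lev)] <- as.numeric(v == lev)
  }
  if (anyNA(X) || any(!is.finite(X))) abort("non-finite feature values")
  if (standardize && !is.null(enc$center))
    X <- sweep(sweep(X, 2, enc$center), 2, enc$scale, "/")
  X
}

fit_scaling <- function(enc, X) {
  enc$center <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  enc$scale <- s
  enc
}

# --- multilayer perceptron -------------------------------------------------

mlp_fit <- function(X, y, hidden = 6L, lr = 0.3, momentum = 0.2,
                    epochs = 500L) {
  n <- nrow(X); d <- ncol(X)
  Y <- cbind(ERROR = as.numeric(y), CORRECT = 1 - as.numeric(y))
  W1 <- matrix(runif((d + 1) * hidden, -0.5, 0.5), d + 1, hidden)
  W2 <- matrix(runif((hidden + 1) * 2, -0.5, 0.5), hidden + 1, 2)
  V1 <- W1 * 0; V2 <- W2 * 0
  Xb <- cbind(1, X)
  for (e in seq_len(epochs)) {
    H <- 1 / (1 + exp(-(Xb %*% W1)))
    Hb <- cbind(1, H)
    Z <- Hb %*% W2
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z); P <- P / rowSums(P)
    D <- (P - Y) / n
    G2 <- crossprod(Hb, D)
    dH <- (D %*% t(W2[-1, , drop = FALSE])) * H * (1 - H)
    G1 <- crossprod(Xb, dH)
    V2 <- momentum * V2 - lr * G2; W2 <- W2 + V2
    V1 <- momentum * V1 - lr * G1; W1 <- W1 + V1
  }
  list(W1 = W1, W2 = W2, hidden = hidden, lr = lr, momentum = momentum,
       epochs = epochs)
}

mlp_prob_error <- function(model, X) {
  H <- 1 / (1 + exp(-(cbind(1, X) %*% model$W1)))
  Z <- cbind(1, H) %*% model$W2
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z); P <- P / rowSums(P)
  P[, 1]
}

# --- ensemble --------------------------------------------------------------

#' Train the plurality-voting error classifier
#'
#' @param bundle An [build_training_bundle()] result (the learning subset
#'   `a` is used) or a labeled feature tibble.
#' @param seed Integer seed (MLP initialization and forest bootstrap).
#' @param mlp_hidden,mlp_lr,mlp_momentum,mlp_epochs MLP hyperparameters:
#'   hidden units, learning rate, momentum, training epochs.
#' @param rf_trees Number of unpruned trees in the random forest.
#' @return An `iped_ensemble` object.
#' @export
train_ensemble <- function(bundle, seed = NULL, mlp_hidden = 6L,
                           mlp_lr = 0.3, mlp_momentum = 0.2,
                           mlp_epochs = 500L, rf_trees = 100L) {
  train <- if (inherits(bundle, "iped_bundle")) bundle$a else as_tibble(bundle)
  if (!"label" %in% names(train) || nrow(train) == 0)
    abort("training data must be non-empty and labeled")
  y <- as_error_logical(train$label)
  if (all(y) || !any(y)) abort("both classes must be present")
  if (!is.null(seed)) set.seed(seed)
  enc <- make_encoder(train)
  X <- encode_features(train, enc, standardize = FALSE)
  enc <- fit_scaling(enc, X)
  Xs <- sweep(sweep(X, 2, enc$center), 2, enc$scale, "/")

  mlp <- mlp_fit(Xs, y, hidden = mlp_hidden, lr = mlp_lr,
                 momentum = mlp_momentum, epochs = mlp_epochs)

  df <- as.data.frame(Xs)
  df$.label <- factor(ifelse(y, "ERROR", "CORRECT"),
                      levels = c("ERROR", "CORRECT"))
  rf_seed <- if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed
  rf <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = rf_trees, mtry = max(1L, floor(sqrt(ncol(Xs)))),
    min.node.size = 1, probability = TRUE, num.threads = 1, seed = rf_seed)

  structure(list(mlp = mlp, rf = rf, encoder = enc,
                 config = list(mlp_hidden = mlp_hidden, mlp_lr = mlp_lr,
                               mlp_momentum = mlp_momentum,
                               mlp_epochs = mlp_epochs, rf_trees = rf_trees,
                               seed = seed),
                 n_train = nrow(train)),
            class = "iped_ensemble")
}

#' @export
print.iped_ensemble <- function(x, ...) {
  cat(sprintf(
    "<iped_ensemble> MLP (%d hidden, lr %g, momentum %g, %d epochs) + random forest (%d trees)\n",
    x$config$mlp_hidden, x$config$mlp_lr, x$config$mlp_momentum,
    x$config$mlp_epochs, x$config$rf_trees))
  cat(sprintf("  trained on %d instances, %d encoded features\n",
              x$n_train, length(x$encoder$names)))
  invisible(x)
}

#' @export
glance.iped_ensemble <- function(x, ...) {
  tibble(n_train = x$n_train, n_features = length(x$encoder$names),
         mlp_hidden = x$config$mlp_hidden, rf_trees = x$config$rf_trees,
         rf_oob_error = x$rf$prediction.error)
}

#' @export
tidy.iped_ensemble <- function(x, ...) {
  tibble(member = c("mlp", "random_forest"),
         parameters = c(sprintf("hidden=%d lr=%g momentum=%g epochs=%d",
                                x$config$mlp_hidden, x$config$mlp_lr,
                                x$config$mlp_momentum, x$config$mlp_epochs),
                        sprintf("trees=%d mtry=%d unpruned",
                                x$config$rf_trees, x$rf$mtry)))
}

#' Predict per-position error confidences with the ensemble
#'
#' @param object An [train_ensemble()] model.
#' @param features A feature tibble in the mode the model was trained on.
#' @param ... Unused.
#' @return A tibble with per-member ERROR confidences (`p_error_mlp`,
#'   `p_error_rf`), the plurality-voting `class` and its winning
#'   `confidence`.
#' @export
predict.iped_ensemble <- function(object, features, ...) {
  n <- nrow(features)
  chunk <- 500000L    # bound peak memory on multi-million-row inputs
  starts <- seq(1L, n, by = chunk)
  parts <- lapply(starts, function(s) {
    rows <- s:min(s + chunk - 1L, n)
    X <- encode_features(features[rows, ], object$encoder, standardize = TRUE)
    p_mlp <- mlp_prob_error(object$mlp, X)
    pr <- predict(object$rf, data = as.data.frame(X),
                  num.threads = 1)$predictions
    vote <- plurality_vote(cbind(p_mlp, pr[, "ERROR"]))
    tibble(p_error_mlp = p_mlp, p_error_rf = pr[, "ERROR"],
           class = vote$class, confidence = vote$confidence)
  })
  list_rbind(parts)
}

# Plurality voting over member ERROR confidences (one column per member):
# the class of the single highest confidence wins; an exact tie between the
# best ERROR and best CORRECT confidence resolves to CORRECT.
plurality_vote <- function(p_error) {
  p_error <- as.matrix(p_error)
  e_conf <- do.call(pmax, as.data.frame(p_error))
  c_conf <- do.call(pmax, as.data.frame(1 - p_error))
  list(class = factor(ifelse(e_conf > c_conf, "ERROR", "CORRECT"),
                      levels = c("ERROR", "CORRECT")),
       confidence = pmax(e_conf, c_conf))
}

#' Predict per-position error masks for contigs
#'
#' A position is masked iff the plurality vote is ERROR and the winning
#' confidence reaches `threshold`.
#'
#' @param model An [train_ensemble()] model.
#' @param features A feature tibble from [extract_features()] (columns
#'   `contig_id` and `pos` are carried through).
#' @param threshold Confidence threshold in `[0, 1]`-ish (values above 1
#'   mask nothing).
#' @return A tibble `contig_id`, `pos`, `masked`.
#' @export
predict_mask <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "iped_ensemble"), is.numeric(threshold))
  pred <- predict(model, features)
  tibble(contig_id = features$contig_id, pos = features$pos,
         masked = pred$class == "ERROR" & pred$confidence >= threshold)
}

#' Aggregate per-contig masks onto a unique-sequence table
#'
#' After dereplication every unique sequence carries several member contigs
#' whose masks may disagree; a position is masked when more than half of the
#' member reads mask it (exact ties are masked).
#'
#' @param uniques A [dereplicate()] table.
#' @param masks A [predict_mask()] tibble over the member contigs.
#' @return `uniques` with its `mask` column filled.
#' @export
aggregate_masks <- function(uniques, masks) {
  membership <- tibble(
    uidx = rep(seq_len(nrow(uniques)), lengths(uniques$member_ids)),
    contig_id = unlist(uniques$member_ids, use.names = FALSE))
  n_members <- lengths(uniques$member_ids)
  mm <- inner_join(masks, membership, by = "contig_id")
  agg <- mm |>
    summarise(n_masked = sum(.data$masked), .by = c("uidx", "pos")) |>
    filter(2 * .data$n_masked >= n_members[.data$uidx])
  uniques$mask <- lapply(nchar(uniques$seq), logical)
  if (nrow(agg)) {
    sp <- split(agg$pos, agg$uidx)
    for (k in names(sp)) {
      u <- as.integer(k)
      m <- uniques$mask[[u]]
      m[sp[[k]] + 1L] <- TRUE
      uniques$mask[[u]] <- m
    }
  }
  uniques
}

#' Save or load a trained ensemble
#'
#' The model directory holds a YAML manifest with the configuration and
#' encoder plus the fitted members; reloading reproduces predictions
#' bit-identically.
#'
#' @param model An `iped_ensemble`.
#' @param dir Model directory.
#' @export
write_ensemble <- function(model, dir) {
  stopifnot(inherits(model, "iped_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(format = "iped_ensemble", version = 1L,
                        config = model$config,
                        features = model$encoder$names),
                   file.path(dir, "manifest.yaml"))
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  manifest <- file.path(dir, "manifest.yaml")
  if (!file.exists(manifest)) abort(sprintf("no model manifest under %s", dir))
  m <- yaml::read_yaml(manifest)
  if (!identical(m$format, "iped_ensemble"))
    abort("not an iped_ensemble model directory")
  readRDS(file.path(dir, "model.rds"))
}
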