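# two well-separated Gaussian blobs as a linearly separable toy problem
blob_instances <- function(n = 200, gap = 6, seed = 91) {
  set.seed(seed)
  half <- n / 2
  tibble::tibble(
    fwd_qual = c(rnorm(half, 10), rnorm(half, 10 + gap)),
    rev_qual = c(rnorm(half, 30), rnorm(half, 30 - gap)),
    label = factor(c(rep("ERROR", half), rep("CORRECT", half)),
                   levels = c("ERROR", "CORRECT")))
}

test_that("the ensemble fits a separable toy problem perfectly", {
  inst <- blob_instances()
  # verify separability by the margin between the class extremes
  expect_gt(min(inst$fwd_qual[inst$label == "CORRECT"]) -
              max(inst$fwd_qual[inst$label == "ERROR"]), 0)
  model <- train_ensemble(inst, seed = 1)
  pred <- predict(model, inst)
  expect_equal(as.character(pred$class), as.character(inst$label))
})

test_that("training and prediction are deterministic under a seed", {
  inst <- blob_instances(gap = 2)
  m1 <- train_ensemble(inst, seed = 2)
  m2 <- train_ensemble(inst, seed = 2)
  p1 <- predict(m1, inst)
  p2 <- predict(m2, inst)
  expect_identical(p1, p2)
})

test_that("plurality voting picks the class of the highest confidence", {
  v <- ipedr:::plurality_vote(cbind(mlp = c(0.9, 0.2, 0.5, 0.4),
                                    rf = c(0.4, 0.3, 0.5, 0.45)))
  # MLP ERROR 0.9 beats RF CORRECT 0.7 -> ERROR
  expect_equal(as.character(v$class[1]), "ERROR")
  expect_equal(v$confidence[1], 0.9)
  # both members CORRECT -> CORRECT
  expect_equal(as.character(v$class[2]), "CORRECT")
  expect_equal(v$confidence[2], 0.8)
  # exact tie resolves to CORRECT (do not mask)
  expect_equal(as.character(v$class[3]), "CORRECT")
  # 0.55 CORRECT vs 0.45+0.4 ERROR -> CORRECT wins at 0.6
  expect_equal(as.character(v$class[4]), "CORRECT")
  expect_equal(v$confidence[4], 0.6)
})

test_that("mask thresholds behave at the extremes", {
  inst <- blob_instances()
  model <- train_ensemble(inst, seed = 3)
  feats <- dplyr::mutate(inst[, c("fwd_qual", "rev_qual")],
                         contig_id = "c1", pos = dplyr::row_number() - 1L)
  m0 <- predict_mask(model, feats, threshold = 0)
  pred <- predict(model, feats)
  expect_equal(m0$masked, pred$class == "ERROR")
  m2 <- predict_mask(model, feats, threshold = 1.1)
  expect_false(any(m2$masked))
})

test_that("feature-width mismatches with the model are hard errors", {
  model <- train_ensemble(blob_instances(), seed = 4)
  expect_error(predict(model, tibble::tibble(fwd_qual = 1)),
               "missing|mismatch")
})

test_that("models survive a save/load round trip bit-identically", {
  inst <- blob_instances(gap = 2)
  model <- train_ensemble(inst, seed = 5)
  dir <- withr::local_tempdir()
  write_ensemble(model, dir)
  back <- read_ensemble(dir)
  expect_identical(predict(model, inst), predict(back, inst))
})

test_that("mask aggregation uses a majority with ties masked", {
  u <- tibble::tibble(id = c("u1", "u2"), seq = c("ACGT", "TTTT"),
                      abundance = c(2L, 3L),
                      member_ids = list(c("a", "b"), c("c", "d", "e")),
                      mask = list(logical(4), logical(4)))
  masks <- tibble::tibble(
    contig_id = rep(c("a", "b", "c", "d", "e"), each = 4),
    pos = rep(0:3, 5),
    masked = c(TRUE, TRUE, FALSE, FALSE,    # a
               TRUE, FALSE, FALSE, FALSE,   # b
               TRUE, TRUE, FALSE, FALSE,    # c
               TRUE, FALSE, FALSE, FALSE,   # d
               FALSE, FALSE, TRUE, FALSE))  # e
  out <- aggregate_masks(u, masks)
  # u1: pos0 2/2 masked; pos1 1/2 = exact tie -> masked
  expect_equal(out$mask[[1]], c(TRUE, TRUE, FALSE, FALSE))
  # u2: pos0 2/3 -> masked; pos1 1/3, pos2 1/3 -> unmasked
  expect_equal(out$mask[[2]], c(TRUE, FALSE, FALSE, FALSE))
})
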