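test_that("masked distance counts unmasked differences only", {
  expect_equal(masked_distance("ACGT", "ACGT"), 0L)
  expect_equal(masked_distance("ACGT", "AGGT"), 1L)
  expect_equal(masked_distance("ACGT", "AGGT",
                               mask_a = c(FALSE, TRUE, FALSE, FALSE)), 0L)
  expect_equal(masked_distance("ACGT", "AGGT",
                               mask_b = c(FALSE, TRUE, FALSE, FALSE)), 0L)
  expect_equal(masked_distance("AC-T", "ACG-"), 2L)  # gap vs base counts
  expect_equal(masked_distance("AC-T", "AC-A"), 1L)  # gap-gap never counts
  expect_error(masked_distance("ACGT", "ACG"), "equal length")
})

test_that("masked distance is symmetric and monotone under masking", {
  set.seed(61)
  for (k in 1:100) {
    len <- sample(10:60, 1)
    a <- random_seq(len); b <- random_seq(len)
    ma <- runif(len) < 0.2; mb <- runif(len) < 0.2
    expect_equal(masked_distance(a, b, ma, mb), masked_distance(b, a, mb, ma))
    expect_gte(masked_distance(a, b), masked_distance(a, b, ma, mb))
    expect_equal(masked_distance(a, b, ma, mb), bf_masked_distance(a, ma, b, mb))
  }
})

test_that("allowed_diffs is 1 per 100 nt, floored, clamped to 1", {
  expect_equal(allowed_diffs(250), 2L)
  expect_equal(allowed_diffs(430), 4L)
  expect_equal(allowed_diffs(50), 1L)
  expect_equal(allowed_diffs(100), 1L)
  expect_equal(allowed_diffs(199), 1L)
})

test_that("a rare 1-off sequence merges into the abundant one", {
  a <- "ACGTACGTAC"
  b <- sub("C", "T", a)
  u <- tibble::tibble(id = c("A", "B"), seq = c(a, b),
                      abundance = c(100L, 5L))
  res <- precluster(u, diffs = 1)
  out <- revert_and_emit(res)
  expect_equal(nrow(out), 1L)
  expect_equal(out$seq, a)
  expect_equal(out$abundance, 105L)
  expect_equal(sort(out$member_ids[[1]]), c("A", "B"))
  mm <- tidy(res)
  expect_equal(mm$representative_id[mm$id == "B"], "A")
  expect_equal(mm$distance[mm$id == "B"], 1L)
})

test_that("a singleton table passes through unchanged", {
  u <- tibble::tibble(id = "A", seq = "ACGT", abundance = 3L)
  res <- precluster(u, diffs = 1)
  expect_equal(revert_and_emit(res)$abundance, 3L)
  expect_false(any(tidy(res)$merged))
})

test_that("precluster matches the brute-force oracle on random tables", {
  set.seed(62)
  for (k in 1:30) {
    n <- sample(5:30, 1)
    len <- sample(20:60, 1)
    u <- random_unique_table(n, len)
    diffs <- sample(1:3, 1)
    res <- precluster(u, diffs = diffs)
    bf <- bf_precluster(u$seq, u$abundance, u$mask, rep(diffs, n))

    got <- tidy(res)
    sorted_ids <- u$id[bf$order]
    expect_equal(got$id, sorted_ids)
    expect_equal(got$representative_id, sorted_ids[bf$rep_of])
    out <- revert_and_emit(res)
    expect_equal(sum(out$abundance), sum(u$abundance))  # conservation
    bf_tab <- tibble::tibble(id = sorted_ids[bf$is_rep],
                             abundance = as.integer(bf$abund[bf$is_rep]))
    expect_equal(out$abundance[order(out$id)],
                 bf_tab$abundance[order(bf_tab$id)])
    expect_true(all(out$seq %in% u$seq))                # mask reversion
  }
})

test_that("empty masks reproduce the plain Pre-cluster baseline", {
  set.seed(63)
  for (k in 1:5) {
    u <- random_unique_table(15, 40, mask_rate = 0.15)
    u0 <- u
    u0$mask <- lapply(seq_len(nrow(u)), function(i) logical(40))
    base <- precluster(u0, diffs = 2)
    noarg <- precluster(u0[, c("id", "seq", "abundance", "member_ids")],
                        diffs = 2)
    expect_equal(tidy(base), tidy(noarg))
  }
})

test_that("auto diffs uses the ungapped length", {
  set.seed(64)
  u <- random_unique_table(6, 250)
  res <- precluster(u, diffs = "auto")
  mm <- tidy(res)
  expect_true(all(mm$distance[mm$merged] <= 2L))   # 250 nt -> 2 diffs
  expect_error(precluster(tibble::tibble(id = c("a", "b"),
                                         seq = c("ACGT", "ACG"),
                                         abundance = c(2L, 1L))),
               "equal length")
})
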