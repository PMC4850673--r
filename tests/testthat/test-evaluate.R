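test_that("error rate is errors over bases, abundance-weighted", {
  set.seed(101)
  ref <- random_seq(100)
  same <- tibble::tibble(id = "a", seq = ref, abundance = 5L)
  expect_equal(error_rate(same, c(r = ref))$error_rate, 0)

  ch <- strsplit(ref, "")[[1]]
  ch[40] <- setdiff(c("A", "C", "G", "T"), ch[40])[1]
  one_sub <- tibble::tibble(id = "b", seq = paste(ch, collapse = ""),
                            abundance = 1L)
  expect_equal(error_rate(one_sub, c(r = ref))$error_rate, 0.01)

  both <- dplyr::bind_rows(same, one_sub)
  r <- error_rate(both, c(r = ref))
  expect_equal(r$total_errors, 1)
  expect_equal(r$total_bases, 600)
  expect_equal(r$error_rate, 1 / 600)
})

test_that("insertions and deletions count toward the printed definition", {
  set.seed(102)
  ref <- random_seq(299)
  # 2 insertions and 1 deletion, placed far apart -> a 300 nt query
  q <- paste0(substr(ref, 1, 50), "A", substr(ref, 51, 150),
              substr(ref, 152, 220), "T", substr(ref, 221, 299))
  expect_equal(nchar(q), 300L)
  r <- error_rate(tibble::tibble(id = "x", seq = q, abundance = 1L),
                  c(r = ref))
  expect_equal(r$per_seq$ins, 2L)
  expect_equal(r$per_seq$del, 1L)
  expect_equal(r$error_rate, 3 / 300)
})

test_that("error rate is invariant to duplicating every abundance", {
  sim <- small_sim(n_pairs = 40, seed = 17)
  u <- dereplicate(merge_pairs(sim$pairs))
  u <- u[nchar(u$seq) == 430, ]
  r1 <- error_rate(u, sim$refs)
  u2 <- u
  u2$abundance <- u2$abundance * 2L
  r2 <- error_rate(u2, sim$refs)
  expect_equal(r1$error_rate, r2$error_rate)
  expect_equal(r2$total_errors, 2 * r1$total_errors)
})

test_that("the simulator's truth count matches the recovered error count", {
  # substitution-only profile, full overlap disabled (fwd read = amplicon)
  set.seed(103)
  refs <- synth_references(n = 4, length = 240)
  prof <- error_profile(read_len = 120, amplicon_len = 240, q_start = 18,
                        q_end = 18, jitter = 0, rev_penalty = 0,
                        ggc_drop = 0)
  sim <- simulate_mock(refs, 80, prof, seed = 19)
  # evaluate the forward reads directly against the amplicon starts
  fwd_tab <- dplyr::summarise(
    dplyr::mutate(sim$pairs, seq = fwd_seq),
    abundance = dplyr::n(), id = seq[1], .by = seq)
  half_refs <- tibble::tibble(id = refs$id, seq = substr(refs$seq, 1, 120))
  r <- error_rate(fwd_tab, half_refs)
  n_fwd_truth <- sum(sim$truth$read == "fwd")
  expect_equal(r$total_errors, n_fwd_truth)
})

test_that("positionwise errors localize and sum back to the total", {
  set.seed(104)
  ref <- random_seq(80)
  ch <- strsplit(ref, "")[[1]]
  ch[25] <- setdiff(c("A", "C", "G", "T"), ch[25])[1]
  tab <- tibble::tibble(id = c("a", "b"),
                        seq = c(ref, paste(ch, collapse = "")),
                        abundance = c(3L, 2L))
  pw <- positionwise_error(tab, c(r = ref))
  expect_equal(nrow(pw), 80L)
  expect_equal(which(pw$errors > 0), 25L)
  expect_equal(sum(pw$errors), 2)   # abundance-weighted
  agg <- error_rate(tab, c(r = ref))
  expect_equal(sum(pw$errors), agg$total_errors)
  # error-free input gives an all-zero vector
  pw0 <- positionwise_error(tab[1, ], c(r = ref))
  expect_true(all(pw0$errors == 0))
})

test_that("forced all-false masks make the masked pipeline equal the baseline", {
  set.seed(105)
  sim <- small_sim(n_pairs = 60, seed = 23)
  u <- dereplicate(merge_pairs(sim$pairs))
  u <- u[nchar(u$seq) == 430, ]
  base <- precluster(u, diffs = "auto")
  u2 <- u
  u2$mask <- lapply(nchar(u2$seq), logical)
  again <- precluster(u2, diffs = "auto")
  expect_equal(revert_and_emit(base), revert_and_emit(again))
})
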