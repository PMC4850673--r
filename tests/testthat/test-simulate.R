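test_that("expected quality follows the decay curve, penalties and clamp", {
  prof <- error_profile(read_len = 100, amplicon_len = 180, q_start = 38,
                        q_end = 20, rev_penalty = 5, ggc_drop = 8,
                        ggc_span = 5, jitter = 0)
  expect_equal(expected_quality("fwd", 0, prof), 38)
  expect_equal(expected_quality("fwd", 99, prof), 20)
  # reverse = forward - rev_penalty (away from the clamp)
  expect_equal(expected_quality("rev", 0, prof),
               expected_quality("fwd", 0, prof) - 5)
  # GGC drop applies to the `ggc_span` positions after the motif
  ctx <- paste0("AAGGC", strrep("T", 95))
  base <- expected_quality("fwd", 6, prof)
  expect_equal(expected_quality("fwd", 6, prof, context = ctx), base - 8)
  far <- expected_quality("fwd", 40, prof)
  expect_equal(expected_quality("fwd", 40, prof, context = ctx), far)
  # clamped into [q_min, q_max]
  prof2 <- error_profile(read_len = 100, amplicon_len = 180, q_start = 45,
                         q_end = 0, jitter = 0)
  expect_equal(expected_quality("fwd", 0, prof2), 40)
  expect_equal(expected_quality("fwd", 99, prof2), 2)
})

test_that("zero pairs give empty outputs", {
  set.seed(71)
  refs <- synth_references(n = 3, length = 120)
  sim <- simulate_mock(refs, 0, error_profile(read_len = 60,
                                              amplicon_len = 120))
  expect_equal(nrow(sim$pairs), 0L)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("the error-free profile injects zero errors", {
  sim <- small_sim(n_pairs = 200, preset = "error_free")
  expect_equal(nrow(sim$truth), 0L)
  amp <- setNames(sim$refs$seq, sim$refs$id)
  expect_equal(sim$pairs$fwd_seq,
               unname(substr(amp[sim$pairs$ref_id], 1, 250)))
})

test_that("same seed reproduces byte-identical outputs", {
  set.seed(72)
  refs <- synth_references(n = 4, length = 150)
  prof <- error_profile(read_len = 80, amplicon_len = 150)
  s1 <- simulate_mock(refs, 50, prof, seed = 5)
  s2 <- simulate_mock(refs, 50, prof, seed = 5)
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in c("R1.fastq", "R2.fastq", "refs.fasta", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("a simulation directory round-trips through read_simulation", {
  set.seed(77)
  refs <- synth_references(n = 3, length = 150)
  prof <- error_profile(read_len = 80, amplicon_len = 150)
  sim <- simulate_mock(refs, 30, prof, seed = 6)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_simulation(dir)
  expect_equal(back$pairs[, c("id", "fwd_seq", "rev_seq", "ref_id")],
               sim$pairs[, c("id", "fwd_seq", "rev_seq", "ref_id")])
  expect_equal(back$pairs$fwd_qual, sim$pairs$fwd_qual)
  expect_equal(as.data.frame(back$truth), as.data.frame(sim$truth))
  expect_equal(back$refs, sim$refs)
  expect_equal(back$profile$miscall, sim$profile$miscall)
  expect_equal(back$profile$read_len, sim$profile$read_len)
})

test_that("every truth record is a real read-vs-template disagreement", {
  set.seed(73)
  refs <- synth_references(n = 3, length = 150)
  prof <- error_profile(read_len = 80, amplicon_len = 150, q_start = 25,
                        q_end = 15)
  sim <- simulate_mock(refs, 60, prof, seed = 9)
  expect_gt(nrow(sim$truth), 0)
  amp <- setNames(sim$refs$seq, sim$refs$id)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    pair <- sim$pairs[sim$pairs$id == tr$id, ]
    read <- if (tr$read == "fwd") pair$fwd_seq else pair$rev_seq
    a <- amp[[pair$ref_id]]
    template <- if (tr$read == "fwd") substr(a, 1, 80)
                else revcomp1(substr(a, 150 - 80 + 1, 150))
    expect_equal(substr(read, tr$pos + 1, tr$pos + 1), tr$obs_base)
    expect_equal(substr(template, tr$pos + 1, tr$pos + 1), tr$true_base)
    expect_true(tr$obs_base != tr$true_base)
  }
})

test_that("substitutions favour the fluorophore-confusable partner", {
  set.seed(74)
  refs <- synth_references(n = 2, length = 200)
  prof <- error_profile(read_len = 100, amplicon_len = 200, q_start = 12,
                        q_end = 12, jitter = 0, rev_penalty = 0,
                        ggc_drop = 0)
  sim <- simulate_mock(refs, 400, prof, seed = 10)
  partner <- c(A = "C", C = "A", G = "T", T = "G")
  frac <- mean(sim$truth$obs_base == partner[sim$truth$true_base])
  expect_gt(frac, 0.55)   # profile default puts 0.6 on the partner
  expect_lt(frac, 0.65)
})

test_that("reverse reads carry more errors than forward reads", {
  set.seed(75)
  refs <- synth_references(n = 3, length = 200)
  prof <- error_profile(read_len = 100, amplicon_len = 200, q_start = 30,
                        q_end = 20, rev_penalty = 6)
  sim <- simulate_mock(refs, 2000, prof, seed = 12)
  counts <- table(sim$truth$read)
  expect_gt(counts[["rev"]], counts[["fwd"]])
})

test_that("realized error fraction matches the Phred expectation at Q=30", {
  set.seed(76)
  refs <- synth_references(n = 3, length = 150)
  prof <- error_profile(read_len = 75, amplicon_len = 150, q_start = 30,
                        q_end = 30, rev_penalty = 0, ggc_drop = 0,
                        jitter = 0)
  sim <- simulate_mock(refs, 2000, prof, seed = 13)
  n_bases <- 2000 * 2 * 75
  p <- 1e-3
  se <- sqrt(p * (1 - p) / n_bases)
  expect_lt(abs(nrow(sim$truth) / n_bases - p), 3 * se)
})
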