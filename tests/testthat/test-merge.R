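# The merge rule: outside the overlap the covering read wins; inside it,
# agreement keeps the base at the max quality, an N defers to the other
# read, and a conflict goes to the higher-quality read only when the Phred
# difference reaches q_delta (else N at quality 0).
#
# Toy geometry used below: 30 nt amplicon, 20 nt reads. The forward read
# covers amplicon positions 1..20 and the reverse read 11..30, so the
# overlap is 11..20. A reverse-read sequencing position p sits at contig
# position 10 + (20 - p + 1) = 31 - p.

test_that("identical fully overlapping reads give an all-MATCH contig", {
  set.seed(20)
  s <- random_seq(250)
  pair <- toy_pair(s, rep(40L, 250), revcomp1(s), rep(40L, 250))
  ctg <- merge_pairs(pair)
  expect_equal(nrow(ctg), 1L)
  expect_equal(ctg$length, 250L)
  expect_equal(ctg$seq, s)
  ov <- overlap_status(ctg)
  expect_true(all(ov$overlap == "MATCH"))
})

test_that("conflicting overlap bases follow the quality-difference rule", {
  set.seed(21)
  amp <- random_seq(30)
  fwd <- substr(amp, 1, 20)
  rev_true <- revcomp1(substr(amp, 11, 30))
  ch <- strsplit(rev_true, "")[[1]]
  ch[15] <- setdiff(c("A", "C", "G", "T"), ch[15])[1]  # contig position 16
  rev_err <- paste(ch, collapse = "")

  # quality difference >= q_delta: the higher-quality (forward) read wins
  pair <- toy_pair(fwd, rep(40L, 20), rev_err, rep(30L, 20))
  ctg <- merge_pairs(pair, min_overlap = 5, q_delta = 6)
  expect_equal(ctg$length, 30L)
  expect_equal(ctg$seq, amp)
  ov <- overlap_status(ctg)
  expect_equal(as.character(ov$overlap[16]), "CONFLICT")
  expect_equal(sum(ov$overlap == "CONFLICT"), 1L)
  expect_equal(sum(ov$overlap == "NOT_OVERLAP"), 20L)

  # quality difference below q_delta: ambiguous N at the conflict
  pair2 <- toy_pair(fwd, rep(30L, 20), rev_err, rep(28L, 20))
  ctg2 <- merge_pairs(pair2, min_overlap = 5, q_delta = 6)
  expect_equal(substr(ctg2$seq, 16, 16), "N")
  expect_true(ctg2$has_n)

  # reverse read much better than forward: the reverse base (an error
  # relative to the amplicon, but the rule only sees qualities) wins
  pair3 <- toy_pair(fwd, rep(20L, 20), rev_err, rep(38L, 20))
  ctg3 <- merge_pairs(pair3, min_overlap = 5, q_delta = 6)
  expect_equal(substr(ctg3$seq, 16, 16), chartr("ACGT", "TGCA", ch[15]))
})

test_that("an N in the overlap defers to the other read (UNKNOWN)", {
  set.seed(22)
  amp <- random_seq(30)
  fwd <- substr(amp, 1, 20)
  ch <- strsplit(revcomp1(substr(amp, 11, 30)), "")[[1]]
  ch[15] <- "N"                                        # contig position 16
  pair <- toy_pair(fwd, rep(35L, 20), paste(ch, collapse = ""), rep(35L, 20))
  ctg <- merge_pairs(pair, min_overlap = 5)
  expect_equal(ctg$seq, amp)
  ov <- overlap_status(ctg)
  expect_equal(as.character(ov$overlap[16]), "UNKNOWN")
})

test_that("pairs with no offset reaching min_overlap are culled, not fatal", {
  pair <- toy_pair(strrep("A", 30), rep(30L, 30),
                   strrep("C", 30), rep(30L, 30))
  expect_message(ctg <- merge_pairs(pair, min_overlap = 40), "culled")
  expect_equal(nrow(ctg), 0L)
  expect_equal(attr(ctg, "rejected"), "p1")
})

test_that("merging is deterministic and reconstructs error-free amplicons", {
  sim <- small_sim(n_pairs = 25, preset = "error_free")
  ctg1 <- merge_pairs(sim$pairs)
  ctg2 <- merge_pairs(sim$pairs)
  expect_identical(ctg1, ctg2)
  amp <- setNames(sim$refs$seq, sim$refs$id)
  expect_equal(ctg1$seq, unname(amp[sim$pairs$ref_id]))
  ov <- overlap_status(ctg1)
  in_overlap <- ov$overlap != "NOT_OVERLAP"
  expect_true(all(ov$overlap[in_overlap] == "MATCH"))
  # v34-like geometry: 430 nt contig, 70 nt overlap
  expect_true(all(ctg1$length == 430L))
  expect_equal(sum(in_overlap) / nrow(ctg1), 70)
})
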