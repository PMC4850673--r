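# Brute-force reference implementations used as independent oracles, plus
# small fixture builders. These deliberately share no code with the package
# internals: plain position scans and per-step recomputation.

bf_masked_distance <- function(a, ma, b, mb) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  d <- 0L
  for (i in seq_along(ca)) {
    if (ma[i] || mb[i]) next
    if (ca[i] == "-" && cb[i] == "-") next
    if (ca[i] != cb[i]) d <- d + 1L
  }
  d
}

bf_homopolymer <- function(seq, i) {
  ch <- strsplit(seq, "")[[1]]
  if (ch[i] == "N") return(-1L)
  lo <- i
  while (lo > 1 && ch[lo - 1] == ch[i]) lo <- lo - 1
  hi <- i
  while (hi < length(ch) && ch[hi + 1] == ch[i]) hi <- hi + 1
  if (hi - lo + 1 < 2) 0L else i - lo + 1L
}

bf_mcc <- function(predicted, truth) {
  TP <- 0; FP <- 0; TN <- 0; FN <- 0
  for (i in seq_along(predicted)) {
    if (truth[i] == "ERROR") {
      if (predicted[i] == "ERROR") TP <- TP + 1 else FN <- FN + 1
    } else {
      if (predicted[i] == "ERROR") FP <- FP + 1 else TN <- TN + 1
    }
  }
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  if (den == 0) 0 else (TP * TN - FP * FN) / den
}

# Single-linkage preclustering recomputing all pairwise masked distances at
# every step: sort by abundance descending (ties lexicographic), walk the
# list, compare against all strictly-more-abundant current representatives,
# merge into the smallest-distance one (ties: highest current abundance,
# then earliest), updating abundances immediately.
bf_precluster <- function(seqs, abund, masks, diffs) {
  ord <- order(-abund, seqs)
  seqs <- seqs[ord]; abund <- abund[ord]; masks <- masks[ord]
  n <- length(seqs)
  cur <- abund
  rep_of <- seq_len(n)
  is_rep <- rep(FALSE, n)
  for (i in seq_len(n)) {
    cand <- which(is_rep & cur > cur[i])
    if (length(cand)) {
      d <- vapply(cand, function(j)
        bf_masked_distance(seqs[i], masks[[i]], seqs[j], masks[[j]]),
        integer(1))
      ok <- d <= diffs[i]
      if (any(ok)) {
        cand <- cand[ok]; d <- d[ok]
        best <- cand[d == min(d)]
        best <- best[cur[best] == max(cur[best])]
        j <- best[1]
        cur[j] <- cur[j] + cur[i]
        rep_of[i] <- j
        next
      }
    }
    is_rep[i] <- TRUE
  }
  list(order = ord, rep_of = rep_of, abund = cur, is_rep = is_rep)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# table of near-duplicate unique sequences with random masks
random_unique_table <- function(n, len, mask_rate = 0.1) {
  base <- random_seq(len)
  seqs <- vapply(seq_len(n), function(i) {
    ch <- strsplit(base, "")[[1]]
    k <- sample(0:3, 1)
    if (k > 0) {
      at <- sample(len, k)
      for (p in at) ch[p] <- sample(c("A", "C", "G", "T"), 1)
    }
    paste(ch, collapse = "")
  }, character(1))
  seqs <- make.unique(seqs, sep = "")  # may create non-ACGT tails; redo dups
  dup <- duplicated(seqs) | grepl("[0-9]", seqs)
  while (any(dup)) {
    seqs[dup] <- vapply(seq_len(sum(dup)), function(i) random_seq(len),
                        character(1))
    dup <- duplicated(seqs)
  }
  tibble::tibble(
    id = sprintf("u%03d", seq_len(n)),
    seq = seqs,
    abundance = sample(1:50, n, replace = TRUE),
    member_ids = as.list(sprintf("u%03d", seq_len(n))),
    mask = lapply(seq_len(n), function(i) runif(len) < mask_rate))
}

# a hand-built read pair whose true merge layout is known
toy_pair <- function(fwd, fq, rev_sequencing, rq, id = "p1") {
  tibble::tibble(id = id, fwd_seq = fwd, fwd_qual = list(fq),
                 rev_seq = rev_sequencing, rev_qual = list(rq))
}

revcomp1 <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

small_sim <- function(n_pairs = 60, n_refs = 5, seed = 99, preset = "v34",
                      ...) {
  set.seed(seed)
  prof <- profile_preset(preset, ...)
  refs <- synth_references(n = n_refs, length = prof$amplicon_len)
  simulate_mock(refs, n_pairs, prof, seed = seed + 1)
}
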