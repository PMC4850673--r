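# Reference alignment for labeling and error counting. Scoring: match 1,
# mismatch -1, gap opening -2, gap extension -1 (a length-k gap costs 2+k).
# When query and reference have equal length, candidate references are
# prescreened by ungapped mismatch count; an ungapped comparison with at most
# 3 mismatches is provably score-optimal under this scheme (each fixed
# mismatch gains 2, while any gapped rearrangement of equal-length sequences
# costs at least two gap openings = 6), so its mismatch positions are used
# directly. Otherwise the affine-gap global alignment is
# computed with Biostrings against the best prescreened candidates, batched
# per reference (scores first, one traceback per sequence).

align_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

batch_align <- function(queries, ref, score_only = FALSE) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = align_submat(),
    gapOpening = 2, gapExtension = 1, scoreOnly = score_only)
}

# 0-based error coordinates from one gapped alignment (query/subject strings
# with '-' gaps). Substitutions and inserted query bases are labeled at their
# own query position; a deletion labels the query position immediately left
# of the gap. On the reference, substitutions and deletions sit at the
# affected reference coordinate and insertions at the preceding one.
gapped_errors <- function(pa, sa) {
  p <- seq_chars(pa); s <- seq_chars(sa)
  qcum <- cumsum(p != "-"); rcum <- cumsum(s != "-")
  mis <- p != "-" & s != "-" & p != s
  ins <- p != "-" & s == "-"
  del <- p == "-"
  err <- mis | ins | del
  qpos <- pmax(qcum - 1L, 0L)
  rpos <- integer(length(p))
  rpos[mis | del] <- rcum[mis | del] - 1L
  rpos[ins] <- pmax(rcum[ins] - 1L, 0L)
  list(subs = sum(mis), ins = sum(ins), del = sum(del),
       qpos = qpos[err], rpos = rpos[err])
}

mismatch_positions <- function(a, b) {
  which(charToRaw(a) != charToRaw(b)) - 1L
}

# Align every sequence to its best reference. Returns a tibble with one row
# per sequence: ref_id, identity, subs, ins, del, and 0-based error position
# lists on the query (err_qpos) and the reference (err_rpos).
# `fast_max_mismatch` bounds the ungapped fast path (see header note);
# `top_k` bounds how many prescreened candidates are scored by full
# alignment.
align_to_refs <- function(seqs, refs, top_k = 3L, fast_max_mismatch = 3L) {
  refs <- as_ref_tibble(refs)
  if (nrow(refs) == 0) abort("empty reference set")
  n <- length(seqs)
  out <- tibble(ref_id = character(n), identity = numeric(n),
                subs = integer(n), ins = integer(n), del = integer(n),
                err_qpos = vector("list", n), err_rpos = vector("list", n))
  L <- unique(nchar(seqs))
  equal_len <- length(L) == 1 && all(nchar(refs$seq) == L)

  slow <- seq_len(n)
  cand <- matrix(rep(seq_len(nrow(refs)), each = n), nrow = n)
  if (equal_len) {
    mm <- mismatch_matrix_cpp(seqs, refs$seq)
    best_m <- apply(mm, 1, min)
    fast <- which(best_m <= fast_max_mismatch)
    for (i in fast) {
      j <- which.min(mm[i, ])
      p <- mismatch_positions(seqs[i], refs$seq[j])
      out$ref_id[i] <- refs$id[j]
      out$identity[i] <- 1 - length(p) / L
      out$subs[i] <- length(p)
      out$err_qpos[[i]] <- p
      out$err_rpos[[i]] <- p
    }
    slow <- setdiff(slow, fast)
    k <- min(top_k, nrow(refs))
    cand <- t(apply(mm, 1, function(r) order(r)[seq_len(k)]))
    if (k == 1) cand <- matrix(cand, ncol = 1)
  }
  if (!length(slow)) return(out)

  # scores for every (sequence, candidate) pair, batched per reference
  scores <- matrix(-Inf, n, nrow(refs))
  for (j in sort(unique(as.vector(cand[slow, , drop = FALSE])))) {
    who <- slow[apply(cand[slow, , drop = FALSE] == j, 1, any)]
    scores[who, j] <- batch_align(seqs[who], refs$seq[j], score_only = TRUE)
  }
  best_j <- integer(n)
  for (i in slow) {
    tied <- which(scores[i, ] == max(scores[i, ]))
    if (length(tied) > 1) {   # minimum-error alignment among max-score refs
      errs <- vapply(tied, function(j) {
        al <- batch_align(seqs[i], refs$seq[j])
        ge <- gapped_errors(as.character(Biostrings::alignedPattern(al)),
                            as.character(Biostrings::alignedSubject(al)))
        ge$subs + ge$ins + ge$del
      }, numeric(1))
      best_j[i] <- tied[which.min(errs)]
    } else {
      best_j[i] <- tied
    }
  }

  # one traceback per sequence, batched by winning reference
  for (j in sort(unique(best_j[slow]))) {
    who <- slow[best_j[slow] == j]
    al <- batch_align(seqs[who], refs$seq[j])
    pa <- as.character(Biostrings::alignedPattern(al))
    sa <- as.character(Biostrings::alignedSubject(al))
    pid <- Biostrings::pid(al) / 100
    for (k in seq_along(who)) {
      i <- who[k]
      ge <- gapped_errors(pa[k], sa[k])
      out$ref_id[i] <- refs$id[j]
      out$identity[i] <- pid[k]
      out$subs[i] <- ge$subs; out$ins[i] <- ge$ins; out$del[i] <- ge$del
      out$err_qpos[[i]] <- ge$qpos
      out$err_rpos[[i]] <- ge$rpos
    }
  }
  out
}
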