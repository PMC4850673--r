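# Mock-community paired-end read simulator with a MiSeq-like error profile:
# quality decays along the read, reverse reads are worse than forward reads,
# positions following a GGC motif take a quality drop, and substitution
# probability at each base is 10^(-Q/10) with the miscall biased toward the
# fluorophore-confusable partner (A<->C, G<->T).

#' MiSeq-like error profile for the read simulator
#'
#' @param read_len Read length in bases (2 x 250 bp protocol by default).
#' @param amplicon_len Amplicon length; controls the overlap between the two
#'   reads (`2 * read_len - amplicon_len`). Must be `<= 2 * read_len`.
#' @param q_start,q_end Phred quality at the first and last read position; the
#'   expected quality decays linearly between them.
#' @param rev_penalty Phred points subtracted across the whole reverse read.
#' @param ggc_drop Phred points subtracted for `ggc_span` positions following a
#'   GGC motif in the read sequence.
#' @param ggc_span Number of positions after a GGC motif affected by the drop.
#' @param jitter Half-width of the integer quality jitter added per base.
#' @param q_min,q_max Clamp bounds for realized qualities. Realized Phred of 90
#'   or more is treated as exactly error-free.
#' @param miscall_partner Probability mass a substitution puts on the
#'   fluorophore-confusable partner base; the remainder is split evenly over
#'   the other two bases.
#' @param indel_rate Optional per-base indel probability (0 disables; used for
#'   labeling-robustness experiments only).
#' @return An object of class `iped_profile` (a named list).
#' @export
error_profile <- function(read_len = 250L, amplicon_len = 430L,
                          q_start = 38, q_end = 24, rev_penalty = 8,
                          ggc_drop = 6, ggc_span = 5L, jitter = 2L,
                          q_min = 2, q_max = 40, miscall_partner = 0.6,
                          indel_rate = 0) {
  stopifnot(read_len >= 1, amplicon_len >= 1, amplicon_len <= 2 * read_len,
            q_start >= 0, q_end >= 0, rev_penalty >= 0, ggc_drop >= 0,
            ggc_span >= 0, jitter >= 0, q_min >= 0, q_max >= q_min,
            miscall_partner >= 0, miscall_partner <= 1,
            indel_rate >= 0, indel_rate < 1)
  structure(list(
    read_len = as.integer(read_len), amplicon_len = as.integer(amplicon_len),
    q_start = q_start, q_end = q_end, rev_penalty = rev_penalty,
    ggc_drop = ggc_drop, ggc_span = as.integer(ggc_span),
    jitter = as.integer(jitter), q_min = q_min, q_max = q_max,
    miscall = miscall_matrix(miscall_partner), indel_rate = indel_rate
  ), class = "iped_profile")
}

# 4x4 substitution matrix conditioned on the true base; rows sum to 1 over
# the three alternative bases, diagonal 0.
miscall_matrix <- function(partner_mass) {
  other <- (1 - partner_mass) / 2
  m <- matrix(other, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  diag(m) <- 0
  partner <- c(A = "C", C = "A", G = "T", T = "G")
  for (b in DNA_BASES) m[b, partner[[b]]] <- partner_mass
  m
}

#' Preset error profiles named after common 16S region geometries
#'
#' `"v4"` is fully overlapping (amplicon 250, reads 250), `"v34"` has a 70 nt
#' overlap (amplicon 430) and `"v45"` a 125 nt overlap (amplicon 375).
#' `"error_free"` emits perfect reads (realized Phred 93 everywhere).
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [error_profile()].
#' @export
profile_preset <- function(name = c("v34", "v4", "v45", "error_free"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    v4  = list(read_len = 250L, amplicon_len = 250L),
    v34 = list(read_len = 250L, amplicon_len = 430L),
    v45 = list(read_len = 250L, amplicon_len = 375L),
    error_free = list(read_len = 250L, amplicon_len = 430L,
                      q_start = 93, q_end = 93, rev_penalty = 0,
                      ggc_drop = 0, jitter = 0L, q_max = 93)
  )
  do.call(error_profile, modifyList(base, list(...)))
}

#' @export
print.iped_profile <- function(x, ...) {
  cat(sprintf(
    "<iped_profile> reads 2 x %d nt, amplicon %d nt (overlap %d nt)\n",
    x$read_len, x$amplicon_len, 2L * x$read_len - x$amplicon_len))
  cat(sprintf("  quality %g -> %g (rev -%g, GGC -%g over %d nt, jitter +/-%d, clamp [%g,%g])\n",
              x$q_start, x$q_end, x$rev_penalty, x$ggc_drop, x$ggc_span,
              x$jitter, x$q_min, x$q_max))
  invisible(x)
}

#' Expected Phred quality at a read position under a profile
#'
#' The base curve decays linearly from `q_start` to `q_end` along the read;
#' reverse reads lose `rev_penalty` Phred points, and positions within
#' `ggc_span` bases after a GGC motif in the read sequence lose `ggc_drop`.
#' The result is clamped to `[q_min, q_max]`.
#'
#' @param read `"fwd"` or `"rev"`.
#' @param position 0-based position(s) in the read.
#' @param profile An [error_profile()].
#' @param context The read sequence (sequencing orientation) used to locate
#'   GGC motifs; `NULL` disables the motif term.
#' @return Numeric vector of expected Phred values.
#' @export
expected_quality <- function(read, position, profile, context = NULL) {
  read <- match.arg(read, c("fwd", "rev"))
  stopifnot(all(position >= 0), all(position < profile$read_len))
  rl <- profile$read_len
  slope <- if (rl > 1) (profile$q_end - profile$q_start) / (rl - 1) else 0
  q <- profile$q_start + slope * position
  if (read == "rev") q <- q - profile$rev_penalty
  if (!is.null(context) && profile$ggc_drop > 0 && profile$ggc_span > 0) {
    hit <- ggc_affected(context, profile$ggc_span)
    q <- q - profile$ggc_drop * hit[position + 1L]
  }
  pmin(pmax(q, profile$q_min), profile$q_max)
}

# logical vector over 0-based read positions: within `span` positions after
# the end of a GGC motif
ggc_affected <- function(seq, span) {
  L <- nchar(seq)
  hit <- logical(L)
  starts <- gregexpr("GGC", seq, fixed = TRUE)[[1]]
  if (starts[1] != -1L) {
    for (s in starts) {           # s is 1-based motif start
      lo <- s + 3L                # 1-based first affected position
      hi <- min(L, s + 2L + span)
      if (lo <= hi) hit[lo:hi] <- TRUE
    }
  }
  hit
}

#' Generate synthetic 16S-like reference sequences
#'
#' A random seed sequence is mutated independently per reference so that
#' pairwise identities fall in a controllable band (roughly
#' `1 - 2 * divergence`), emulating the OTU-level distinctness of mock
#' community members.
#'
#' @param n Number of references (mock communities in this style hold 12-21
#'   species).
#' @param length Reference length in bases (defaults to one amplicon).
#' @param divergence Range of per-reference substitution rates from the seed
#'   sequence.
#' @param gc GC content of the seed sequence.
#' @return A tibble with columns `id` and `seq`.
#' @export
synth_references <- function(n = 15L, length = 430L,
                             divergence = c(0.03, 0.05), gc = 0.54) {
  stopifnot(n >= 1, length >= 1, all(divergence >= 0), all(divergence < 1))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seed_chars <- sample(DNA_BASES, length, replace = TRUE, prob = p)
  refs <- vapply(seq_len(n), function(i) {
    rate <- runif(1, divergence[1], divergence[length(divergence)])
    ch <- seed_chars
    hit <- which(runif(length(ch)) < rate)
    for (k in hit) ch[k] <- sample(setdiff(DNA_BASES, ch[k]), 1)
    paste(ch, collapse = "")
  }, character(1))
  tibble(id = sprintf("ref%02d", seq_len(n)), seq = refs)
}

#' Simulate mock-community paired-end reads with known error truth
#'
#' References are sampled according to `composition`; the forward read is the
#' first `read_len` bases of the amplicon and the reverse read the reverse
#' complement of the last `read_len` bases. Per-base qualities are drawn from
#' the profile (with integer jitter) and substitutions injected independently
#' with probability `10^(-Q/10)` using the profile's miscall matrix. Every
#' injected difference is recorded in the truth table.
#'
#' @param refs Reference sequences: a tibble with `id`/`seq` columns, a named
#'   character vector, or a `Biostrings::DNAStringSet`. Each must be at least
#'   `amplicon_len` long.
#' @param n_pairs Number of read pairs to simulate.
#' @param profile An [error_profile()] or [profile_preset()] result.
#' @param composition `NULL` for even (equimolar) composition, `"uneven"` for
#'   a geometric abundance series, or a numeric weight vector over the refs.
#' @param seed Integer seed; the same seed, profile and refs give
#'   byte-identical output.
#' @return An object of class `iped_sim`: a list with tibbles `pairs`
#'   (id, fwd_seq, fwd_qual, rev_seq, rev_qual, ref_id), `truth`
#'   (id, read, pos, true_base, obs_base), `refs` (amplicon-region sequences),
#'   `composition`, plus the profile and seed.
#' @export
simulate_mock <- function(refs, n_pairs, profile = profile_preset("v34"),
                          composition = NULL, seed = NULL) {
  refs <- as_ref_tibble(refs)
  check_scalar_int(n_pairs, "n_pairs", min = 0)
  short <- refs$id[nchar(refs$seq) < profile$amplicon_len]
  if (length(short))
    abort(sprintf("reference(s) shorter than amplicon_len (%d): %s",
                  profile$amplicon_len, paste(short, collapse = ", ")))
  if (!is.null(seed)) set.seed(seed)

  w <- if (is.null(composition)) rep(1, nrow(refs))
       else if (identical(composition, "uneven")) 0.7^(seq_len(nrow(refs)) - 1)
       else {
         stopifnot(is.numeric(composition), length(composition) == nrow(refs),
                   all(composition >= 0), sum(composition) > 0)
         composition
       }
  comp <- tibble(ref_id = refs$id, weight = w / sum(w))

  amp <- substr(refs$seq, 1L, profile$amplicon_len)
  names(amp) <- refs$id
  rl <- profile$read_len
  L <- profile$amplicon_len

  if (n_pairs == 0) {
    return(structure(list(
      pairs = tibble(id = character(), fwd_seq = character(),
                     fwd_qual = list(), rev_seq = character(),
                     rev_qual = list(), ref_id = character()),
      truth = tibble(id = character(), read = character(), pos = integer(),
                     true_base = character(), obs_base = character()),
      refs = tibble(id = refs$id, seq = unname(amp)),
      composition = comp, profile = profile, seed = seed
    ), class = "iped_sim"))
  }

  assign_ref <- sample(refs$id, n_pairs, replace = TRUE, prob = comp$weight)
  ids <- sprintf("read%06d", seq_len(n_pairs))

  pair_rows <- vector("list", nrow(refs))
  truth_rows <- vector("list", 0)
  for (ri in seq_len(nrow(refs))) {
    idx <- which(assign_ref == refs$id[ri])
    if (!length(idx)) next
    a <- amp[[refs$id[ri]]]
    true_fwd <- substr(a, 1L, rl)
    true_rev <- revcomp(substr(a, L - rl + 1L, L))
    f <- sim_reads_one_template(true_fwd, "fwd", length(idx), profile)
    r <- sim_reads_one_template(true_rev, "rev", length(idx), profile)
    pair_rows[[ri]] <- tibble(
      id = ids[idx], fwd_seq = f$seq, fwd_qual = f$qual,
      rev_seq = r$seq, rev_qual = r$qual, ref_id = refs$id[ri])
    for (tb in list(c(list(f$truth), list("fwd")), c(list(r$truth), list("rev")))) {
      tt <- tb[[1]]
      if (nrow(tt)) {
        tt$id <- ids[idx][tt$row]
        tt$read <- tb[[2]]
        truth_rows[[length(truth_rows) + 1]] <-
          tt[, c("id", "read", "pos", "true_base", "obs_base")]
      }
    }
  }
  pairs <- arrange(list_rbind(pair_rows), .data$id)
  truth <- if (length(truth_rows)) arrange(list_rbind(truth_rows),
                                           .data$id, .data$read, .data$pos)
           else tibble(id = character(), read = character(), pos = integer(),
                       true_base = character(), obs_base = character())

  structure(list(pairs = pairs, truth = truth,
                 refs = tibble(id = refs$id, seq = unname(amp)),
                 composition = comp, profile = profile, seed = seed),
            class = "iped_sim")
}

# Simulate n copies of one template read. Returns list(seq, qual, truth)
# where truth has columns row/pos/true_base/obs_base (0-based read pos).
sim_reads_one_template <- function(template, read, n, profile) {
  rl <- profile$read_len
  base_q <- expected_quality(read, 0:(rl - 1), profile, context = template)
  qmat <- matrix(rep(as.integer(round(base_q)), each = n), nrow = n)
  if (profile$jitter > 0) {
    qmat <- qmat + matrix(sample(-profile$jitter:profile$jitter, n * rl,
                                 replace = TRUE), nrow = n)
  }
  qmat <- pmin(pmax(qmat, as.integer(ceiling(profile$q_min))),
               as.integer(floor(profile$q_max)))
  p <- 10^(-qmat / 10)
  p[qmat >= 90] <- 0  # Phred >= 90 treated as exactly error-free
  err <- matrix(runif(n * rl) < p, nrow = n)

  true_chars <- seq_chars(template)
  cmat <- matrix(rep(true_chars, each = n), nrow = n)
  hits <- which(err, arr.ind = TRUE)
  if (nrow(hits)) {
    tb <- true_chars[hits[, 2]]
    obs <- character(nrow(hits))
    for (b in DNA_BASES) {
      k <- which(tb == b)
      if (length(k))
        obs[k] <- sample(DNA_BASES, length(k), replace = TRUE,
                         prob = profile$miscall[b, ])
    }
    cmat[hits] <- obs
    truth <- tibble(row = hits[, 1], pos = hits[, 2] - 1L,
                    true_base = tb, obs_base = obs)
    truth <- arrange(truth, .data$row, .data$pos)
  } else {
    truth <- tibble(row = integer(), pos = integer(),
                    true_base = character(), obs_base = character())
  }
  seqs <- apply(cmat, 1, paste, collapse = "")
  if (profile$indel_rate > 0) {
    ed <- apply_indels(seqs, profile$indel_rate)
    seqs <- ed
  }
  list(seq = seqs,
       qual = lapply(seq_len(n), function(i) qmat[i, ]),
       truth = truth)
}

# Optional crude indel editing for labeling-robustness experiments: each base
# independently deleted or duplicated with probability `rate`; reads are
# re-padded/trimmed to their original length with random bases.
apply_indels <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- seq_chars(s)
    u <- runif(length(ch))
    out <- character(0)
    for (i in seq_along(ch)) {
      if (u[i] < rate / 2) next                      # deletion
      out <- c(out, ch[i])
      if (u[i] >= rate / 2 && u[i] < rate)           # insertion (duplication)
        out <- c(out, ch[i])
    }
    n <- nchar(s)
    if (length(out) < n)
      out <- c(out, sample(DNA_BASES, n - length(out), replace = TRUE))
    paste(out[seq_len(n)], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

as_ref_tibble <- function(refs) {
  if (inherits(refs, "DNAStringSet"))
    return(tibble(id = names(refs) %||% as.character(seq_along(refs)),
                  seq = as.character(refs)))
  if (is.data.frame(refs)) {
    stopifnot(all(c("id", "seq") %in% names(refs)))
    return(as_tibble(refs[, c("id", "seq")]))
  }
  if (is.character(refs)) {
    if (length(refs) == 0) abort("empty reference set")
    return(tibble(id = names(refs) %||% as.character(seq_along(refs)),
                  seq = unname(refs)))
  }
  abort("`refs` must be a tibble (id, seq), named character vector or DNAStringSet")
}

#' @export
print.iped_sim <- function(x, ...) {
  cat(sprintf("<iped_sim> %d read pairs from %d references, %d truth records\n",
              nrow(x$pairs), nrow(x$refs), nrow(x$truth)))
  invisible(x)
}

#' Write a simulation to disk as FASTQ/FASTA/TSV
#'
#' Emits `R1.fastq`, `R2.fastq`, `refs.fasta` (amplicon-region references),
#' `truth.tsv`, `composition.tsv` and `profile.yaml` under `dir`.
#'
#' @param sim An [simulate_mock()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "iped_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fastq(sim$pairs$id, sim$pairs$fwd_seq, sim$pairs$fwd_qual,
              file.path(dir, "R1.fastq"), suffix = "/1")
  write_fastq(sim$pairs$id, sim$pairs$rev_seq, sim$pairs$rev_qual,
              file.path(dir, "R2.fastq"), suffix = "/2")
  write_fasta(setNames(sim$refs$seq, sim$refs$id), file.path(dir, "refs.fasta"))
  readr::write_tsv(sim$pairs[, c("id", "ref_id")], file.path(dir, "reads.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$composition, file.path(dir, "composition.tsv"))
  prof <- sim$profile
  prof$miscall <- as.vector(prof$miscall)
  yaml::write_yaml(prof, file.path(dir, "profile.yaml"))
  invisible(dir)
}

#' @rdname write_simulation
#' @details `read_simulation()` rebuilds an `iped_sim` object from a
#'   directory written by `write_simulation()`.
#' @export
read_simulation <- function(dir) {
  pairs <- read_paired_fastq(file.path(dir, "R1.fastq"),
                             file.path(dir, "R2.fastq"))
  reads <- readr::read_tsv(file.path(dir, "reads.tsv"),
                           show_col_types = FALSE)
  pairs <- left_join(pairs, reads, by = "id")
  truth <- readr::read_tsv(
    file.path(dir, "truth.tsv"), show_col_types = FALSE,
    col_types = readr::cols(id = "c", read = "c", pos = "i",
                            true_base = "c", obs_base = "c"))
  p <- yaml::read_yaml(file.path(dir, "profile.yaml"))
  profile <- do.call(error_profile, c(
    p[intersect(names(p), setdiff(names(formals(error_profile)),
                                  "miscall_partner"))]))
  profile$miscall <- matrix(unlist(p$miscall), 4, 4,
                            dimnames = list(DNA_BASES, DNA_BASES))
  structure(list(
    pairs = pairs,
    truth = as_tibble(truth),
    refs = read_fasta(file.path(dir, "refs.fasta")),
    composition = readr::read_tsv(file.path(dir, "composition.tsv"),
                                  show_col_types = FALSE),
    profile = profile, seed = NULL
  ), class = "iped_sim")
}
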