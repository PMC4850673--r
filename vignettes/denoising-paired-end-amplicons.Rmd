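---
title: "Denoising paired-end amplicon reads: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising paired-end amplicon reads: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the method it implements: the
two-stage denoiser for Illumina MiSeq paired-end amplicon reads, the
simulator used to validate it, and every place where the implementation had
to fix a convention the method description leaves open.

## The procedure

**Stage 0 — merging.** Paired reads are merged into a contig by an ungapped
offset scan (no indels are assumed inside the overlap, consistent with the
substitution-dominated MiSeq error spectrum). Outside the overlap the
covering read supplies base and quality. Inside it, agreeing bases keep the
higher of the two qualities; if one call is ambiguous the other read wins;
two conflicting non-ambiguous calls go to the higher-quality read when the
Phred difference is at least `q_delta`, and otherwise become `N` with
quality 0. Contigs containing `N` are culled before dereplication, so an
unresolvable conflict is effectively a rejection of the read pair.

**Stage 1 — per-position error classification.** Every contig position is
described by six features: position in the forward read, forward
homopolymer status (−1 ambiguous, 0 singleton, else 1-based index within a
run of ≥ 2), forward Phred score; position in the reverse read and reverse
Phred score; and the overlap status (`NOT_OVERLAP`, `MATCH`, `CONFLICT`,
`UNKNOWN`). A full 17-feature mode additionally carries, per read, a
GGC-motif flag and the homopolymer status and quality of the neighbouring
positions; a correlation-based feature-selection routine
(`select_features()`) is provided to reduce the full set. Labels for
training come from aligning contigs of a mock community against its
reference sequences. The classifier is a plurality-voting ensemble of a
multilayer perceptron and a random forest; each member outputs per-class
confidences and the class of the single highest confidence wins, with exact
ties resolved to CORRECT so that uncertainty never masks a position.

**Stage 2 — masked preclustering.** Unique sequences (with abundances from
dereplication) are processed in abundance-descending order. A sequence is
merged into a strictly-more-abundant representative when their masked
Hamming distance is at most `max(1, floor(L/100))` (1 difference per
100 nt); positions masked on *either* sequence never count. Abundances
update immediately, the nearest qualifying representative wins (ties:
highest current abundance, then earliest), and after clustering the
representative sequences are emitted exactly as they were read in — masking
is a transient flag, never a sequence edit.

Assumptions worth stating: sequences entering preclustering are
same-region amplicons of equal length (the pipeline screens to the modal
contig length, mirroring standard screening steps); the error model is
substitution-dominated; and reference sequences are available for training
labels and error-rate evaluation (the mock-community setting).

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `min_overlap` | 10 nt | minimum read overlap for a merge; below it the pair is culled |
| `q_delta` | 6 Phred | quality difference needed to resolve a conflicting overlap call; smaller differences give `N` |
| `ratio_a` | 1:3 | error:non-error ratio of the learning subset (the ratio that balances sensitivity against specificity) |
| learning caps | 5,000 / 15,000 | maximum erroneous / non-erroneous learning instances (after dereplication of identical feature rows) |
| MLP | 6 hidden units, lr 0.3, momentum 0.2, 500 epochs | stated ensemble configuration; epochs/batch updates and input standardization are implementation conventions stored with the model |
| random forest | 100 unpruned trees, `floor(sqrt(p))` features per split | "unpruned" is the stated property; size and mtry are conventions exposed in `train_ensemble()` |
| `threshold` | 0.5 | minimum winning ERROR confidence for masking |
| `diffs` | `"auto"` | preclustering allowance; `auto` = `max(1, floor(L/100))` on the ungapped length, reproducing the 2-diff convention at 250 nt and 4 at 430 nt |
| `min_identity` | 0.9 | labeling alignment gate; contigs below it against every reference are skipped |

## What the simulator emulates — and what it does not

`simulate_mock()` draws read pairs from synthetic 16S-like references
(default 15 references at 92–97% pairwise identity, even composition).
Per-base Phred values follow a linear decay from `q_start` (38) to `q_end`
(24), minus a reverse-read penalty (8), minus a GGC-motif drop (6 Phred
over the 5 following positions), plus small integer jitter (±2), clamped to
[2, 40]. Substitutions are injected independently with probability
`10^(-Q/10)`, with 60% of the mass on the fluorophore-confusable partner
(A↔C, G↔T). The defaults were chosen so that a v34-like run lands near
field-typical raw contig error rates (a few errors per 1,000 bases) and a
make.contigs-style merge culls a realistic fraction of pairs through
unresolved conflicts.

Realized Phred ≥ 90 is treated as exactly error-free; this makes the
`error_free` preset (`q = 93`) deterministic at zero errors for every seed
rather than "zero with high probability".

The simulator does **not** model chimeras, contamination, PCR point errors,
flow-cell physics, or (by default) indels; an optional per-base
`indel_rate` exists only for labeling-robustness experiments, and its truth
records are approximate. Consequently, passing tests show that the
implementation behaves correctly under a clean substitution-only error
model — on such data masked preclustering can drive the measured error rate
to zero, which real mock communities (with chimeras and reference-set
imperfections) will not reproduce.

## Numerical and design choices

* **Offset scoring.** The overlap scan maximizes *matches − mismatches*,
  not the raw match count: a long spurious overlap accrues ~25% random
  matches and would otherwise outscore a short true overlap (on the
  v34-like geometry this mis-merges essentially every pair). Ties prefer
  the larger overlap, then the smaller offset.
* **Alignment for labeling/error counting.** Scoring is match +1, mismatch
  −1, gap open −2, gap extend −1, minimum-error among max-score alignments.
  For equal-length query/reference the best reference is prescreened by
  ungapped mismatch count; when that count is ≤ 3 the ungapped comparison
  is provably score-optimal (fixing a mismatch gains 2; any gapped
  rearrangement of equal-length sequences costs at least two gap openings,
  i.e. 6), so its mismatch positions are used directly. Otherwise the
  affine-gap alignment runs against the top prescreened candidates
  (batched, one traceback per sequence). Indel labeling: an inserted base
  is flagged at its own position, a deletion at the position immediately
  left of the gap.
* **Feature selection.** Greedy forward search on the CFS merit
  `k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)` with absolute Pearson correlations, per
  cross-validation fold, majority vote across folds. Class correlations
  below `2/sqrt(n)` are shrunk to zero: the merit of `k` uncorrelated noise
  features grows like `sqrt(k)`, so without this floor the search would
  absorb pure noise.
* **Mask aggregation.** After dereplication a unique sequence may carry
  members with disagreeing masks; a position is masked when more than half
  of the member reads mask it, with exact ties masked.
* **Training-time dereplication.** Identical (features, label) rows
  collapse to one. With six discretized features this saturates: the
  distinct-row space is bounded by positions × realized quality values ×
  homopolymer × overlap states, so the learning-set caps may be
  unreachable on synthetic data and deeper simulation does not help —
  beyond saturation it only multiplies feature cells that occur in *both*
  classes, which dereplication then flattens to one contradictory row per
  class. The bundle builder warns and proceeds at the achievable size, and
  the study-scale runs train ~1,100 erroneous instances from 8,000 pairs.
* **Determinism.** All stochastic stages (simulation, bundle shuffling, MLP
  initialization, forest bootstrap) are seeded; merging, feature
  extraction, preclustering and evaluation are deterministic, so identical
  configurations reproduce identical outputs byte for byte.
* **Degenerate inputs.** Empty reference sets, single-class training data,
  unequal-length precluster inputs and feature-width mismatches are hard
  errors; empty masks reproduce the plain Pre-cluster baseline exactly;
  an error-free simulation yields error rate 0 with reductions reported as
  not applicable.

## Problem sizes

The validation suite trains on an 8,000-pair simulated run (about 3.4
million contig positions before instance dereplication) and evaluates the
full raw / Pre-cluster / masked comparison on a 20,000-pair v34-like run;
oracle-equivalence properties use hundreds of random small tables, and
determinism is double-checked on a 2,000-pair run. These sizes keep the
whole suite within a coffee break on one CPU while leaving every stage at
or above the scale where its asymptotic behaviour (derep saturation,
precluster pool collapse) is visible.

## Known limitations

* Equal-length, same-region amplicons are required for preclustering;
  aligning mixed-region data is out of scope.
* The error-rate evaluator assumes the reference set covers the community
  (mock-community setting); chimera handling is not implemented.
* Plurality voting is not guaranteed to dominate both of its members at a
  fixed operating point; on held-out data it can land a hair below the
  weaker member's MCC while improving the confidence ranking.
* The masked-precluster stage inherits single-linkage's greedy semantics:
  merge decisions depend on processing order (fixed deterministically by
  abundance, then sequence) and are not globally optimal.
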