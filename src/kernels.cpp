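#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Ungapped overlap-offset scan for merging a forward read with the
// reverse-complemented reverse read. Offset o is the start of rev relative
// to fwd (may be negative when the reverse read overhangs on the left).
// Among offsets with overlap >= min_overlap the one maximizing
// matches - mismatches in the overlap wins (a raw match count would favour
// long spurious overlaps over short true ones); ties prefer the larger
// overlap, then the smaller offset. Returns offset, matches and overlap
// length, or overlap = -1 when no offset reaches min_overlap.
// [[Rcpp::export]]
List best_offset_cpp(std::string fwd, std::string rev, int min_overlap) {
  const int lf = fwd.size(), lr = rev.size();
  int best_o = 0, best_m = 0, best_ov = -1;
  int best_s = INT_MIN;
  for (int o = -(lr - min_overlap); o <= lf - min_overlap; ++o) {
    int lo = std::max(0, o);
    int hi = std::min(lf, o + lr);
    int ov = hi - lo;
    if (ov < min_overlap) continue;
    int m = 0;
    for (int i = lo; i < hi; ++i)
      if (fwd[i] == rev[i - o]) ++m;
    int s = 2 * m - ov;  // matches - mismatches
    if (s > best_s || (s == best_s && ov > best_ov)) {
      best_s = s; best_m = m; best_ov = ov; best_o = o;
    }
  }
  return List::create(_["offset"] = best_o, _["matches"] = best_m,
                      _["overlap"] = best_ov);
}

// Mismatch counts between every sequence and every reference; all strings
// must share one length. Used to prescreen candidate references before
// affine-gap alignment.
// [[Rcpp::export]]
IntegerMatrix mismatch_matrix_cpp(CharacterVector seqs, CharacterVector refs) {
  const int n = seqs.size(), m = refs.size();
  if (n == 0 || m == 0) return IntegerMatrix(n, m);
  const int L = LENGTH(STRING_ELT(seqs, 0));
  std::vector<const char*> sp(n), rp(m);
  for (int i = 0; i < n; ++i) {
    if (LENGTH(STRING_ELT(seqs, i)) != L) stop("sequences must share one length");
    sp[i] = CHAR(STRING_ELT(seqs, i));
  }
  for (int j = 0; j < m; ++j) {
    if (LENGTH(STRING_ELT(refs, j)) != L) stop("references must share the sequence length");
    rp[j] = CHAR(STRING_ELT(refs, j));
  }
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      int d = 0;
      const char *a = sp[i], *b = rp[j];
      for (int k = 0; k < L; ++k) if (a[k] != b[k]) ++d;
      out(i, j) = d;
    }
  return out;
}

// Abundance-sorted single-linkage preclustering with masked distances.
// Inputs come pre-sorted (abundance descending, ties lexicographic by
// sequence). masks is an n x L logical matrix; a masked position on either
// sequence never counts toward the distance. Returns for each input the
// 1-based index of the representative it merged into (itself if none) and
// the masked distance of the merge (-1 if unmerged).
// [[Rcpp::export]]
List precluster_cpp(CharacterVector seqs, LogicalMatrix masks,
                    NumericVector abund, IntegerVector diffs) {
  const int n = seqs.size();
  if (n == 0) return List::create(_["target"] = IntegerVector(0),
                                  _["dist"] = IntegerVector(0));
  const int L = LENGTH(STRING_ELT(seqs, 0));
  if (masks.nrow() != n || masks.ncol() != L)
    stop("mask matrix does not match the sequence table");
  std::vector<const char*> sp(n);
  for (int i = 0; i < n; ++i) {
    if (LENGTH(STRING_ELT(seqs, i)) != L)
      stop("sequences must be equal length; align them first");
    sp[i] = CHAR(STRING_ELT(seqs, i));
  }
  std::vector<double> cur(abund.begin(), abund.end());
  std::vector<bool> is_rep(n, false);
  IntegerVector target(n), dist(n);
  for (int i = 0; i < n; ++i) {
    int best_j = -1, best_d = diffs[i] + 1;
    double best_ab = -1.0;
    for (int j = 0; j < i; ++j) {
      if (!is_rep[j]) continue;
      if (!(cur[j] > cur[i])) continue;  // strictly more abundant
      int lim = best_d;  // must beat or tie the current best
      int d = 0;
      const char *a = sp[i], *b = sp[j];
      for (int k = 0; k < L; ++k) {
        if (a[k] != b[k] && !masks(i, k) && !masks(j, k)) {
          if (++d > lim) break;
        }
      }
      if (d > diffs[i] || d > best_d) continue;
      if (d < best_d || cur[j] > best_ab) {  // smaller distance, then higher abundance, then earliest
        best_d = d; best_j = j; best_ab = cur[j];
      }
    }
    if (best_j >= 0) {
      cur[best_j] += cur[i];
      target[i] = best_j + 1;
      dist[i] = best_d;
    } else {
      is_rep[i] = true;
      target[i] = i + 1;
      dist[i] = -1;
    }
  }
  return List::create(_["target"] = target, _["dist"] = dist);
}
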