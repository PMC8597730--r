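#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-state DP) over protein sequences,
// plus the nucleotide-level read primitives (pair merging, expected-error
// trimming) that the metagenome screen runs on millions of reads.

static const int NEG = -100000000;

struct ScoreTable {
  int tab[128][128];
  ScoreTable(const IntegerMatrix& sub, const std::vector<std::string>& alpha) {
    std::memset(tab, 0, sizeof(tab));
    int n = alpha.size();
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        unsigned char a = alpha[i][0], b = alpha[j][0];
        tab[a][b] = sub(i, j);
      }
    }
  }
  inline int s(unsigned char a, unsigned char b) const { return tab[a][b]; }
};

struct AlnStats {
  int score;
  int matches;
  int columns;        // all alignment columns
  int interior_cols;  // columns excluding terminal gap runs
  std::string aln_a, aln_b;
};

// states: 0 = M (diagonal), 1 = X (gap in b, consumes a, "up"),
//         2 = Y (gap in a, consumes b, "left")
// Tie-breaking is deterministic and, on exact score ties, favors gap states
// (X, then Y, then M) and gap-run continuation. This keeps co-optimal
// traceback from converting a terminal gap run into an internal one (e.g. by
// snapping a fragment's end residue onto a distant identical residue), which
// would corrupt the terminal-gap-excluded identity of a short query aligned
// inside a long reference.
static AlnStats gotoh(const std::string& a, const std::string& b,
                      const ScoreTable& st, int gap_open, int gap_extend,
                      bool want_strings) {
  int m = a.size(), n = b.size();
  int W = n + 1;
  std::vector<int> M((m + 1) * W, NEG), X((m + 1) * W, NEG), Y((m + 1) * W, NEG);
  std::vector<unsigned char> tbM((m + 1) * W, 0), tbX((m + 1) * W, 0), tbY((m + 1) * W, 0);
  M[0] = 0;
  for (int i = 1; i <= m; ++i) {
    X[i * W] = gap_open + i * gap_extend;
    tbX[i * W] = 1;
  }
  for (int j = 1; j <= n; ++j) {
    Y[j] = gap_open + j * gap_extend;
    tbY[j] = 2;
  }
  for (int i = 1; i <= m; ++i) {
    const unsigned char ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      int idx = i * W + j, dg = (i - 1) * W + (j - 1), up = (i - 1) * W + j,
          lf = i * W + (j - 1);
      // M
      int best = M[dg]; unsigned char src = 0;
      if (X[dg] > best) { best = X[dg]; src = 1; }
      if (Y[dg] > best) { best = Y[dg]; src = 2; }
      M[idx] = best + st.s(ai, b[j - 1]);
      tbM[idx] = src;
      // X: gap in b (consume a); ties prefer continuing the gap run
      int vM = M[up] + gap_open + gap_extend;
      int vX = X[up] + gap_extend;
      int vY = Y[up] + gap_open + gap_extend;
      best = vX; src = 1;
      if (vM > best) { best = vM; src = 0; }
      if (vY > best) { best = vY; src = 2; }
      X[idx] = best; tbX[idx] = src;
      // Y: gap in a (consume b); ties prefer continuing the gap run
      vM = M[lf] + gap_open + gap_extend;
      vX = X[lf] + gap_open + gap_extend;
      vY = Y[lf] + gap_extend;
      best = vY; src = 2;
      if (vM > best) { best = vM; src = 0; }
      if (vX > best) { best = vX; src = 1; }
      Y[idx] = best; tbY[idx] = src;
    }
  }
  int end = m * W + n;
  int state = 1, score = X[end];
  if (Y[end] > score) { score = Y[end]; state = 2; }
  if (M[end] > score) { score = M[end]; state = 0; }

  // traceback
  std::string ops;  // 'M' diagonal, 'U' up (gap in b), 'L' left (gap in a)
  ops.reserve(m + n);
  int i = m, j = n;
  int matches = 0;
  while (i > 0 || j > 0) {
    int idx = i * W + j;
    if (state == 0) {
      ops.push_back('M');
      if (a[i - 1] == b[j - 1]) ++matches;
      state = tbM[idx]; --i; --j;
    } else if (state == 1) {
      ops.push_back('U');
      state = tbX[idx]; --i;
    } else {
      ops.push_back('L');
      state = tbY[idx]; --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  int cols = ops.size();
  int lead = 0, trail = 0;
  while (lead < cols && ops[lead] != 'M') ++lead;
  while (trail < cols - lead && ops[cols - 1 - trail] != 'M') ++trail;
  AlnStats out;
  out.score = score;
  out.matches = matches;
  out.columns = cols;
  out.interior_cols = cols - lead - trail;
  if (want_strings) {
    out.aln_a.reserve(cols); out.aln_b.reserve(cols);
    int ia = 0, ib = 0;
    for (int k = 0; k < cols; ++k) {
      if (ops[k] == 'M') { out.aln_a.push_back(a[ia++]); out.aln_b.push_back(b[ib++]); }
      else if (ops[k] == 'U') { out.aln_a.push_back(a[ia++]); out.aln_b.push_back('-'); }
      else { out.aln_a.push_back('-'); out.aln_b.push_back(b[ib++]); }
    }
  }
  return out;
}

static std::vector<std::string> alpha_from(const IntegerMatrix& sub) {
  CharacterVector rn = rownames(sub);
  std::vector<std::string> alpha(rn.size());
  for (int i = 0; i < rn.size(); ++i) alpha[i] = as<std::string>(rn[i]);
  return alpha;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, IntegerMatrix sub,
                  int gap_open, int gap_extend) {
  ScoreTable st(sub, alpha_from(sub));
  AlnStats r = gotoh(a, b, st, gap_open, gap_extend, true);
  double ident = r.interior_cols > 0 ? (double)r.matches / r.interior_cols : 0.0;
  return List::create(_["aligned_a"] = r.aln_a, _["aligned_b"] = r.aln_b,
                      _["score"] = r.score, _["identity"] = ident,
                      _["columns"] = r.columns,
                      _["interior_columns"] = r.interior_cols,
                      _["matches"] = r.matches);
}

// All-vs-all identity/score/column matrices (queries x refs).
// [[Rcpp::export]]
List nw_batch_cpp(CharacterVector queries, CharacterVector refs,
                  IntegerMatrix sub, int gap_open, int gap_extend) {
  ScoreTable st(sub, alpha_from(sub));
  int nq = queries.size(), nr = refs.size();
  NumericMatrix ident(nq, nr);
  IntegerMatrix score(nq, nr), cols(nq, nr);
  std::vector<std::string> rv(nr);
  for (int j = 0; j < nr; ++j) rv[j] = as<std::string>(refs[j]);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    for (int j = 0; j < nr; ++j) {
      AlnStats r = gotoh(q, rv[j], st, gap_open, gap_extend, false);
      ident(i, j) = r.interior_cols > 0 ? (double)r.matches / r.interior_cols : 0.0;
      score(i, j) = r.score;
      cols(i, j) = r.interior_cols;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["identity"] = ident, _["score"] = score,
                      _["interior_columns"] = cols);
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C';
    case 'T': return 'A'; case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

// Merge one read pair. r2 is given in sequencing orientation and
// reverse-complemented here. Offset k is the start of revcomp(r2) relative to
// the start of r1 (0-based; negative = staggered to the left). The best
// overlap has the fewest mismatches, ties broken by longer overlap, then by
// smaller |k|, then by k >= 0. Accepted iff overlap >= min_overlap and
// mismatches <= max_diffs. Staggered overhangs are trimmed.
// [[Rcpp::export]]
List merge_pair_cpp(std::string s1, IntegerVector q1, std::string s2,
                    IntegerVector q2, int max_diffs, int min_overlap,
                    bool allow_stagger) {
  int L1 = s1.size(), L2 = s2.size();
  std::string r = revcomp_cpp(s2);
  std::vector<int> qr(L2);
  for (int i = 0; i < L2; ++i) qr[i] = q2[L2 - 1 - i];

  int best_k = 0, best_ov = -1, best_diffs = INT_MAX;
  bool found = false;
  for (int k = -(L2 - 1); k <= L1 - 1; ++k) {
    int lo = std::max(0, k), hi = std::min(L1, k + L2);
    int ov = hi - lo;
    if (ov < min_overlap) continue;  // only qualifying overlaps compete
    bool stagger = (k < 0) || (k + L2 < L1);
    if (stagger && !allow_stagger) continue;
    int diffs = 0;
    for (int p = lo; p < hi; ++p) {
      if (s1[p] != r[p - k]) ++diffs;
      if (diffs > max_diffs) break;
    }
    if (diffs > max_diffs) continue;
    bool better = false;
    if (diffs < best_diffs) better = true;
    else if (diffs == best_diffs) {
      if (ov > best_ov) better = true;
      else if (ov == best_ov) {
        if (std::abs(k) < std::abs(best_k)) better = true;
        else if (std::abs(k) == std::abs(best_k) && k >= 0 && best_k < 0) better = true;
      }
    }
    if (better) { best_k = k; best_ov = ov; best_diffs = diffs; found = true; }
  }
  if (!found) {
    return List::create(_["merged"] = false);
  }
  int k = best_k;
  int lo = std::max(0, k), hi = std::min(L1, k + L2);
  bool stagger = (k < 0) || (k + L2 < L1);
  std::string seq;
  std::vector<int> qual;
  if (!stagger) {
    // r1 prefix + consensus overlap + r2 suffix
    for (int p = 0; p < lo; ++p) { seq.push_back(s1[p]); qual.push_back(q1[p]); }
  }
  for (int p = lo; p < hi; ++p) {
    int p2 = p - k;
    if (s1[p] == r[p2]) {
      seq.push_back(s1[p]);
      qual.push_back(std::max((int)q1[p], qr[p2]));
    } else if (q1[p] >= qr[p2]) {
      seq.push_back(s1[p]); qual.push_back(q1[p]);
    } else {
      seq.push_back(r[p2]); qual.push_back(qr[p2]);
    }
  }
  if (!stagger) {
    for (int p2 = hi - k; p2 < L2; ++p2) { seq.push_back(r[p2]); qual.push_back(qr[p2]); }
  }
  return List::create(_["merged"] = true, _["seq"] = seq,
                      _["qual"] = IntegerVector(qual.begin(), qual.end()),
                      _["overlap"] = best_ov, _["diffs"] = best_diffs,
                      _["offset"] = k);
}

// Longest contiguous window with sum of error probabilities strictly below
// max_ee (two-pointer; leftmost window on ties). Returns 1-based [start, end],
// or c(0, -1) when no base qualifies.
// [[Rcpp::export]]
IntegerVector ee_window_cpp(IntegerVector qual, double max_ee) {
  int n = qual.size();
  std::vector<double> p(n);
  for (int i = 0; i < n; ++i) p[i] = std::pow(10.0, -qual[i] / 10.0);
  int best_len = 0, best_start = 0;
  double s = 0.0;
  int l = 0;
  for (int r = 0; r < n; ++r) {
    s += p[r];
    while (l <= r && s >= max_ee) s -= p[l++];
    int len = r - l + 1;
    if (len > best_len) { best_len = len; best_start = l; }
  }
  if (best_len == 0) return IntegerVector::create(0, -1);
  return IntegerVector::create(best_start + 1, best_start + best_len);
}
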