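#include <Rcpp.h>
#include <unordered_set>
#include <string>
#include <cstring>
using namespace Rcpp;

// Residue order shared with the R side (see aa_alphabet()).
static const char* AA_ORDER = "ACDEFGHIKLMNPQRSTVWY";

static inline void build_index(int* idx) {
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (int i = 0; i < 20; ++i) idx[(unsigned char)AA_ORDER[i]] = i;
}

// Best local alignment score of one peptide against a position-specific
// score matrix S (L match columns x 20 residues, bits), affine gaps:
// a gap of length g costs open + (g-1) * extend. Unknown residues ('X')
// score 0 at every column. Alignments may not start or end in a gap state.
// sp is the column-major score matrix data (L rows); sp[r * L + i - 1]
static double best_score_one(const double* sp, int L, const char* pep, int m,
                             double gap_open, double gap_extend, const int* idx,
                             std::vector<double>& buf) {
  if (m == 0 || L == 0) return 0.0;
  const double NEG = -1e30;
  buf.assign(6 * (m + 1), NEG);
  double* Mprev = buf.data();
  double* Mcur = Mprev + (m + 1);
  double* Xprev = Mcur + (m + 1);
  double* Xcur = Xprev + (m + 1);
  double* Yprev = Xcur + (m + 1);
  double* Ycur = Yprev + (m + 1);
  std::vector<int> ridx(m);
  for (int j = 0; j < m; ++j) ridx[j] = idx[(unsigned char)pep[j]];
  double best = 0.0;
  for (int i = 1; i <= L; ++i) {
    const double* srow = sp + (i - 1);
    Mcur[0] = NEG; Xcur[0] = NEG; Ycur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      int r = ridx[j - 1];
      double s = (r >= 0) ? srow[(size_t)r * L] : 0.0;
      double diag = 0.0;
      if (Mprev[j - 1] > diag) diag = Mprev[j - 1];
      if (Xprev[j - 1] > diag) diag = Xprev[j - 1];
      if (Yprev[j - 1] > diag) diag = Yprev[j - 1];
      Mcur[j] = s + diag;
      if (Mcur[j] > best) best = Mcur[j];
      double x1 = Mprev[j] - gap_open, x2 = Xprev[j] - gap_extend;
      Xcur[j] = x1 > x2 ? x1 : x2;
      double y1 = Mcur[j - 1] - gap_open, y2 = Ycur[j - 1] - gap_extend;
      Ycur[j] = y1 > y2 ? y1 : y2;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_profile_scores(const NumericMatrix& S, const CharacterVector& peptides,
                                 double gap_open, double gap_extend) {
  int idx[256];
  build_index(idx);
  const int L = S.nrow();
  const double* sp = REAL(S);
  const int n = peptides.size();
  NumericVector out(n);
  std::vector<double> buf;
  for (int p = 0; p < n; ++p) {
    const char* pep = CHAR(STRING_ELT(peptides, p));
    out[p] = best_score_one(sp, L, pep, (int)strlen(pep), gap_open,
                            gap_extend, idx, buf);
  }
  return out;
}

// Full alignment with traceback; returns the best-scoring local alignment,
// its profile span, peptide span and the per-column residue string
// ('-' where a profile column is skipped; inserted peptide residues are
// consumed but map to no column).
// [[Rcpp::export]]
List cpp_profile_align(const NumericMatrix& S, const std::string& pep,
                       double gap_open, double gap_extend) {
  int idx[256];
  build_index(idx);
  const int L = S.nrow();
  const double* sp = REAL(S);
  const int m = (int)pep.size();
  const double NEG = -1e30;
  // state matrices, (L+1) x (m+1)
  std::vector<double> M((L + 1) * (m + 1), NEG), X((L + 1) * (m + 1), NEG),
      Y((L + 1) * (m + 1), NEG);
  // traceback: for M, 0=start,1=M,2=X,3=Y; for X, 1=M,2=X; for Y, 1=M,3=Y
  std::vector<signed char> tM((L + 1) * (m + 1), 0), tX((L + 1) * (m + 1), 0),
      tY((L + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= m; ++j) {
      int r = idx[(unsigned char)pep[j - 1]];
      double s = (r >= 0) ? sp[(size_t)r * L + (i - 1)] : 0.0;
      double diag = 0.0; signed char tb = 0;
      if (M[at(i - 1, j - 1)] > diag) { diag = M[at(i - 1, j - 1)]; tb = 1; }
      if (X[at(i - 1, j - 1)] > diag) { diag = X[at(i - 1, j - 1)]; tb = 2; }
      if (Y[at(i - 1, j - 1)] > diag) { diag = Y[at(i - 1, j - 1)]; tb = 3; }
      M[at(i, j)] = s + diag; tM[at(i, j)] = tb;
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
      double x1 = M[at(i - 1, j)] - gap_open, x2 = X[at(i - 1, j)] - gap_extend;
      if (x1 >= x2) { X[at(i, j)] = x1; tX[at(i, j)] = 1; }
      else          { X[at(i, j)] = x2; tX[at(i, j)] = 2; }
      double y1 = M[at(i, j - 1)] - gap_open, y2 = Y[at(i, j - 1)] - gap_extend;
      if (y1 >= y2) { Y[at(i, j)] = y1; tY[at(i, j)] = 1; }
      else          { Y[at(i, j)] = y2; tY[at(i, j)] = 3; }
    }
  }
  if (best <= 0.0 || bi == 0) {
    return List::create(_["score"] = best,
                        _["aligned"] = CharacterVector::create(NA_STRING),
                        _["col_first"] = NA_INTEGER, _["col_last"] = NA_INTEGER,
                        _["pep_first"] = NA_INTEGER, _["pep_last"] = NA_INTEGER);
  }
  // traceback from (bi, bj) in state M
  int i = bi, j = bj, state = 1;  // 1=M,2=X,3=Y
  std::string rev;                // column string, reversed
  int col_first = bi, pep_first = bj;
  bool done = false;
  while (!done) {
    if (state == 1) {
      signed char tb = tM[at(i, j)];
      rev.push_back(pep[j - 1]);
      col_first = i; pep_first = j;
      --i; --j;
      if (tb == 0) done = true; else state = tb;
    } else if (state == 2) {
      signed char tb = tX[at(i, j)];
      rev.push_back('-');
      --i;
      state = tb;
    } else {
      signed char tb = tY[at(i, j)];
      // inserted residue: consumed, no column emitted
      --j;
      state = (tb == 1) ? 1 : 3;
    }
  }
  std::string aligned(rev.rbegin(), rev.rend());
  return List::create(_["score"] = best, _["aligned"] = aligned,
                      _["col_first"] = col_first, _["col_last"] = bi,
                      _["pep_first"] = pep_first, _["pep_last"] = bj);
}

// Rolling 5-bit-per-residue k-mer codes (k <= 12) for allocation-free
// exact-word screening.
static inline bool kmer_hit(const char* s, int len, int k, uint64_t mask,
                            const std::unordered_set<uint64_t>& words) {
  if (len < k) return false;
  uint64_t code = 0;
  for (int i = 0; i < len; ++i) {
    code = ((code << 5) | (uint64_t)((unsigned char)s[i] - 'A')) & mask;
    if (i >= k - 1 && words.count(code)) return true;
  }
  return false;
}

static void index_kmers(const CharacterVector& refs, int k, uint64_t mask,
                        std::unordered_set<uint64_t>& words) {
  for (int r = 0; r < refs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(refs, r));
    int len = (int)strlen(s);
    uint64_t code = 0;
    for (int i = 0; i < len; ++i) {
      code = ((code << 5) | (uint64_t)((unsigned char)s[i] - 'A')) & mask;
      if (i >= k - 1) words.insert(code);
    }
  }
}

// Screen + score every fragment against every marker profile in one pass:
// entry (f, m) is the best local alignment score of fragment f against
// profile m when the fragment shares a k-mer with marker m's references,
// NA otherwise.
// [[Rcpp::export]]
NumericMatrix cpp_score_markers(const CharacterVector& fragments,
                                const List& ref_sets, const List& score_mats,
                                const NumericVector& gap_open,
                                const NumericVector& gap_extend, int k) {
  if (k < 3 || k > 12) stop("k must be in [3, 12]");
  int idx[256];
  build_index(idx);
  const uint64_t mask = (k * 5 >= 64) ? ~0ULL : ((1ULL << (5 * k)) - 1);
  const int n_marker = ref_sets.size();
  std::vector<std::unordered_set<uint64_t>> words(n_marker);
  std::vector<NumericMatrix> mats;
  for (int m = 0; m < n_marker; ++m) {
    index_kmers(as<CharacterVector>(ref_sets[m]), k, mask, words[m]);
    mats.push_back(as<NumericMatrix>(score_mats[m]));
  }
  const int n = fragments.size();
  NumericMatrix out(n, n_marker);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> buf;
  for (int f = 0; f < n; ++f) {
    const char* pep = CHAR(STRING_ELT(fragments, f));
    int len = (int)strlen(pep);
    for (int m = 0; m < n_marker; ++m) {
      if (!kmer_hit(pep, len, k, mask, words[m])) continue;
      out(f, m) = best_score_one(REAL(mats[m]), mats[m].nrow(), pep, len,
                                 gap_open[m], gap_extend[m], idx, buf);
    }
  }
  return out;
}

// Exact k-mer screen: fragment survives iff it shares at least one length-k
// word with any reference peptide. Fragments shorter than k never survive.
// [[Rcpp::export]]
LogicalVector cpp_kmer_screen(const CharacterVector& fragments,
                              const CharacterVector& references, int k) {
  std::unordered_set<std::string> words;
  for (int r = 0; r < references.size(); ++r) {
    std::string ref = as<std::string>(references[r]);
    if ((int)ref.size() < k) continue;
    for (size_t p = 0; p + k <= ref.size(); ++p) words.insert(ref.substr(p, k));
  }
  const int n = fragments.size();
  LogicalVector out(n);
  for (int f = 0; f < n; ++f) {
    std::string frag = as<std::string>(fragments[f]);
    bool hit = false;
    if ((int)frag.size() >= k) {
      for (size_t p = 0; p + k <= frag.size() && !hit; ++p)
        if (words.count(frag.substr(p, k))) hit = true;
    }
    out[f] = hit;
  }
  return out;
}
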