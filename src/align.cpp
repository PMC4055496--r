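#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Semi-global (free end gap) pairwise DNA alignment.
// Scoring: match +1, mismatch -1, gap -2 per gap column; terminal gaps free.
// N (or any IUPAC ambiguity) matches nothing and scores as a mismatch.
// Traceback tie-break: diagonal (substitution) preferred over gaps, then the
// gap consuming the first sequence over the one consuming the second; the
// traceback start is the earliest maximum on the last row, then on the last
// column.

static const int GAP = -2;

// A=0, C=1, G=2, T=3, N/ambiguity=4; anything else -> -1 (invalid)
static inline int encode_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case 'N': case 'n':
  case 'R': case 'r': case 'Y': case 'y': case 'S': case 's':
  case 'W': case 'w': case 'K': case 'k': case 'M': case 'm':
  case 'B': case 'b': case 'D': case 'd': case 'H': case 'h':
  case 'V': case 'v':
    return 4;
  default: return -1;
  }
}

static std::vector<int8_t> encode_seq(const std::string& s, const char* what) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int b = encode_base(s[i]);
    if (b < 0)
      stop("non-IUPAC character '%s' at position %d of %s",
           std::string(1, s[i]).c_str(), (int)(i + 1), what);
    v[i] = (int8_t)b;
  }
  return v;
}

// reusable DP workspace (R is single-threaded)
struct Workspace {
  std::vector<int16_t> S;   // full score matrix, row-major (n+1) x (m+1)
  std::vector<int16_t> t;   // per-row scratch (diag/up phase)
  std::vector<int16_t> bb;  // reference as int16 (match comparisons vectorise)
};
static Workspace& ws() {
  static Workspace w;
  return w;
}

struct AlnResult {
  int score;
  int matches;   // matched columns on the aligned (non-terminal) path
  int columns;   // aligned columns excluding terminal gaps
  std::string aln_a, aln_b; // full aligned strings incl. terminal gaps
};

// Scores fit int16 comfortably (|score| <= 2 * max length, lengths < 16k).
// The row recurrence is split in two phases so the diag/up phase carries no
// serial dependency (auto-vectorises); the left-gap phase is a cheap decay
// scan. Directions are not stored: the traceback re-derives each step from
// the score matrix with the documented preference order (diag, up, left).
static AlnResult align_core(const std::vector<int8_t>& a,
                            const std::vector<int8_t>& b,
                            const std::string* sa, const std::string* sb) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  if (n > 16000 || m > 16000) stop("sequences longer than 16 kb not supported");
  Workspace& w = ws();
  if (w.S.size() < (size_t)(n + 1) * (m + 1))
    w.S.resize((size_t)(n + 1) * (m + 1));
  if ((int)w.t.size() < m + 1) w.t.resize(m + 1);
  if ((int)w.bb.size() < m) w.bb.resize(m);
  int16_t* S = w.S.data();
  int16_t* tp = w.t.data();
  int16_t* bs = w.bb.data();
  const int8_t* A = a.data();
  const int8_t* B = b.data();
  for (int j = 0; j < m; ++j) bs[j] = (B[j] < 4) ? B[j] : (int16_t)9;

  for (int j = 0; j <= m; ++j) S[j] = 0;
  for (int i = 1; i <= n; ++i) {
    const int16_t* pr = S + (size_t)(i - 1) * (m + 1);
    int16_t* cu = S + (size_t)i * (m + 1);
    const int16_t ai = (A[i - 1] < 4) ? A[i - 1] : (int16_t)8; // 8 != 9: N never matches
    for (int j = 1; j <= m; ++j) {
      const int16_t s = (ai == bs[j - 1]) ? (int16_t)1 : (int16_t)-1;
      const int16_t ds = (int16_t)(pr[j - 1] + s);
      const int16_t ug = (int16_t)(pr[j] + GAP);
      tp[j] = ds > ug ? ds : ug;
    }
    cu[0] = 0;
    int16_t run = 0;
    for (int j = 1; j <= m; ++j) {
      const int16_t lg = (int16_t)(run + GAP);
      int16_t v = tp[j];
      if (lg > v) v = lg;
      cu[j] = v;
      run = v;
    }
  }
  // best boundary cell: earliest maximum on last row, then last column
  const int16_t* lastrow = S + (size_t)n * (m + 1);
  int best_i = n, best_j = 0, best_score = lastrow[0];
  for (int j = 1; j <= m; ++j)
    if (lastrow[j] > best_score) { best_score = lastrow[j]; best_j = j; }
  for (int i = 1; i < n; ++i)
    if (S[(size_t)i * (m + 1) + m] > best_score) {
      best_score = S[(size_t)i * (m + 1) + m]; best_i = i; best_j = m;
    }

  int i = best_i, j = best_j;
  int matches = 0, columns = 0;
  std::string ra, rb;
  const bool want_strings = sa != nullptr;
  if (want_strings) {
    for (int k = n; k > best_i; --k) { ra.push_back((*sa)[k - 1]); rb.push_back('-'); }
    for (int k = m; k > best_j; --k) { ra.push_back('-'); rb.push_back((*sb)[k - 1]); }
  }
  while (i > 0 && j > 0) {
    const int16_t here = S[(size_t)i * (m + 1) + j];
    const bool mt = (A[i - 1] == B[j - 1] && A[i - 1] < 4);
    const int16_t s = mt ? 1 : -1;
    if (here == (int16_t)(S[(size_t)(i - 1) * (m + 1) + (j - 1)] + s)) {
      matches += mt ? 1 : 0;
      ++columns;
      if (want_strings) { ra.push_back((*sa)[i - 1]); rb.push_back((*sb)[j - 1]); }
      --i; --j;
    } else if (here == (int16_t)(S[(size_t)(i - 1) * (m + 1) + j] + GAP)) {
      ++columns;
      if (want_strings) { ra.push_back((*sa)[i - 1]); rb.push_back('-'); }
      --i;
    } else {
      ++columns;
      if (want_strings) { ra.push_back('-'); rb.push_back((*sb)[j - 1]); }
      --j;
    }
  }
  if (want_strings) {
    while (i > 0) { ra.push_back((*sa)[i - 1]); rb.push_back('-'); --i; }
    while (j > 0) { ra.push_back('-'); rb.push_back((*sb)[j - 1]); --j; }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
  }
  AlnResult r;
  r.score = best_score; r.matches = matches; r.columns = columns;
  r.aln_a = ra; r.aln_b = rb;
  return r;
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b) {
  std::vector<int8_t> ea = encode_seq(a, "first sequence");
  std::vector<int8_t> eb = encode_seq(b, "second sequence");
  AlnResult r = align_core(ea, eb, &a, &b);
  return List::create(_["aligned_a"] = r.aln_a, _["aligned_b"] = r.aln_b,
                      _["score"] = r.score, _["matches"] = r.matches,
                      _["columns"] = r.columns);
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'a': c = 't'; break;
    case 'C': c = 'G'; break; case 'c': c = 'g'; break;
    case 'G': c = 'C'; break; case 'g': c = 'c'; break;
    case 'T': c = 'A'; break; case 't': c = 'a'; break;
    default: break; // N etc. unchanged
    }
  }
  return r;
}

// Ungapped same-coordinate identity used only to pick the query orientation.
static double ungapped_identity(const std::vector<int8_t>& a,
                                const std::vector<int8_t>& b) {
  const size_t L = std::min(a.size(), b.size());
  if (L == 0) return 0.0;
  size_t match = 0;
  for (size_t i = 0; i < L; ++i)
    if (a[i] == b[i] && a[i] < 4) ++match;
  return (double)match / (double)L;
}

// Align one query against every reference; returns score/identity per
// reference plus the orientation used (1 forward, -1 reverse complement).
// [[Rcpp::export(name = ".scan_panel_cpp")]]
List scan_panel_cpp(std::string query, CharacterVector refs,
                    bool check_orientation) {
  const int nr = refs.size();
  if (nr == 0) stop("reference panel is empty");
  std::vector<std::vector<int8_t> > erefs(nr);
  for (int k = 0; k < nr; ++k)
    erefs[k] = encode_seq(std::string(refs[k]), "reference");
  std::vector<int8_t> q = encode_seq(query, "query");
  int orientation = 1;
  if (check_orientation) {
    std::vector<int8_t> qr = encode_seq(revcomp(query), "query");
    double best_f = -1.0, best_r = -1.0;
    for (int k = 0; k < nr; ++k) {
      double f = ungapped_identity(q, erefs[k]);
      double r = ungapped_identity(qr, erefs[k]);
      if (f > best_f) best_f = f;
      if (r > best_r) best_r = r;
    }
    if (best_r > best_f) { q = qr; orientation = -1; }
  }
  NumericVector score(nr), identity(nr), matches(nr), columns(nr);
  for (int k = 0; k < nr; ++k) {
    AlnResult r = align_core(q, erefs[k], nullptr, nullptr);
    score[k] = r.score;
    matches[k] = r.matches;
    columns[k] = r.columns;
    identity[k] = r.columns > 0 ? (double)r.matches / (double)r.columns : 0.0;
  }
  return List::create(_["score"] = score, _["identity"] = identity,
                      _["matches"] = matches, _["columns"] = columns,
                      _["orientation"] = orientation);
}
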