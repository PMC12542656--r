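// Affine-gap pairwise alignment kernels (Gotoh) used by the recruitment,
// annotation, dereplication and chimera stages. A gap of length g costs
// gap_open + g * gap_ext (BLAST-style existence/extension).
#include <Rcpp.h>
#include <set>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

const int NEG = -100000000;

inline void build_lookup(const std::string& alphabet, int* lut) {
  // unknown characters map to the last alphabet symbol (X or N): never a match
  for (int i = 0; i < 256; ++i) lut[i] = (int)alphabet.size() - 1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    lut[(unsigned char)alphabet[i]] = (int)i;
}

List empty_result() {
  return List::create(_["score"] = 0, _["matches"] = 0, _["aln_len"] = 0,
                      _["q_start"] = 0, _["q_end"] = 0, _["s_start"] = 0,
                      _["s_end"] = 0, _["q_aln"] = "", _["s_aln"] = "");
}

} // namespace

// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(std::string q, std::string s, IntegerMatrix sub,
               std::string alphabet, int gap_open, int gap_ext,
               bool global) {
  int m = (int)q.size(), n = (int)s.size();
  if (m == 0 || n == 0) {
    if (!global) return empty_result();
    // a fully gapped global alignment
    std::string qa(m, '-'), sa(n, '-');
    for (int i = 0; i < m; ++i) qa[i] = q[i];
    for (int j = 0; j < n; ++j) sa[j] = s[j];
    int len = std::max(m, n);
    int sc = (len == 0) ? 0 : -(gap_open + gap_ext * len);
    std::string qg = (m == 0) ? std::string(n, '-') : qa;
    std::string sg = (n == 0) ? std::string(m, '-') : sa;
    return List::create(_["score"] = sc, _["matches"] = 0, _["aln_len"] = len,
                        _["q_start"] = 0, _["q_end"] = m, _["s_start"] = 0,
                        _["s_end"] = n, _["q_aln"] = qg, _["s_aln"] = sg);
  }
  int lut[256];
  build_lookup(alphabet, lut);
  int unk = (int)alphabet.size() - 1;
  std::vector<int> qi(m), si(n);
  for (int i = 0; i < m; ++i) qi[i] = lut[(unsigned char)q[i]];
  for (int j = 0; j < n; ++j) si[j] = lut[(unsigned char)s[j]];
  // flat copy of the scoring matrix avoids accessor overhead in the loop
  int A = (int)alphabet.size();
  std::vector<int> subf(A * A);
  for (int a = 0; a < A; ++a)
    for (int b = 0; b < A; ++b) subf[a * A + b] = sub(a, b);

  int ncol = n + 1;
  size_t sz = (size_t)(m + 1) * ncol;
  std::vector<int> M(sz), X(sz), Y(sz);
  // traceback: for M, 0 = fresh start (local) / origin, 1..3 = predecessor state
  std::vector<unsigned char> tm(sz, 0), tx(sz, 0), ty(sz, 0);

  M[0] = 0; X[0] = NEG; Y[0] = NEG;
  for (int j = 1; j <= n; ++j) {
    M[j] = global ? NEG : 0;
    X[j] = NEG;
    Y[j] = global ? -(gap_open + gap_ext * j) : NEG;
    ty[j] = (j == 1) ? 1 : 3;
  }
  for (int i = 1; i <= m; ++i) {
    size_t r = (size_t)i * ncol;
    M[r] = global ? NEG : 0;
    X[r] = global ? -(gap_open + gap_ext * i) : NEG;
    Y[r] = NEG;
    tx[r] = (i == 1) ? 1 : 2;
  }

  int best = global ? NEG : 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    size_t r = (size_t)i * ncol, rp = r - ncol;
    const int* subrow = &subf[qi[i - 1] * A];
    for (int j = 1; j <= n; ++j) {
      int sc = subrow[si[j - 1]];
      int a = M[rp + j - 1], b = X[rp + j - 1], c = Y[rp + j - 1];
      int mm = a; unsigned char mt = 1;
      if (b > mm) { mm = b; mt = 2; }
      if (c > mm) { mm = c; mt = 3; }
      if (!global && mm < 0) { mm = 0; mt = 0; } // fresh local start
      int mv = mm + sc;
      if (!global && mv < 0) { mv = 0; mt = 0; }
      M[r + j] = mv; tm[r + j] = mt;
      int xo = M[rp + j] - gap_open - gap_ext;
      int xe = X[rp + j] - gap_ext;
      if (xo >= xe) { X[r + j] = xo; tx[r + j] = 1; }
      else          { X[r + j] = xe; tx[r + j] = 2; }
      int yo = M[r + j - 1] - gap_open - gap_ext;
      int ye = Y[r + j - 1] - gap_ext;
      if (yo >= ye) { Y[r + j] = yo; ty[r + j] = 1; }
      else          { Y[r + j] = ye; ty[r + j] = 3; }
      if (!global && M[r + j] > best) { best = M[r + j]; bi = i; bj = j; }
    }
  }

  int state = 1;
  if (global) {
    size_t e = (size_t)m * ncol + n;
    best = M[e]; state = 1;
    if (X[e] > best) { best = X[e]; state = 2; }
    if (Y[e] > best) { best = Y[e]; state = 3; }
    bi = m; bj = n;
  } else if (best <= 0) {
    return empty_result();
  }

  std::string qa, sa;
  int i = bi, j = bj, matches = 0;
  bool done = false;
  while (!done) {
    if (i == 0 && j == 0) break;
    if (state == 1) {
      if (i == 0 || j == 0) break; // should not happen
      unsigned char t = tm[(size_t)i * ncol + j];
      qa.push_back(q[i - 1]); sa.push_back(s[j - 1]);
      if (q[i - 1] == s[j - 1] && qi[i - 1] != unk) ++matches;
      --i; --j;
      if (t == 0) {
        if (global && (i > 0 || j > 0)) state = (i > 0) ? 2 : 3;
        else done = true;
      } else state = t;
    } else if (state == 2) {
      unsigned char t = tx[(size_t)i * ncol + j];
      qa.push_back(q[i - 1]); sa.push_back('-');
      --i;
      if (i == 0 && j > 0) state = 3;       // global border
      else state = (t == 1) ? 1 : 2;
    } else {
      unsigned char t = ty[(size_t)i * ncol + j];
      qa.push_back('-'); sa.push_back(s[j - 1]);
      --j;
      if (j == 0 && i > 0) state = 2;       // global border
      else state = (t == 1) ? 1 : 3;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["aln_len"] = (int)qa.size(),
                      _["q_start"] = i, _["q_end"] = bi,
                      _["s_start"] = j, _["s_end"] = bj,
                      _["q_aln"] = qa, _["s_aln"] = sa);
}

// Count of shared length-k exact substrings between two strings (seed test).
// [[Rcpp::export(name = ".cpp_shared_kmers")]]
int cpp_shared_kmers(std::string a, std::string b, int k) {
  if ((int)a.size() < k || (int)b.size() < k) return 0;
  std::set<std::string> sa;
  for (int i = 0; i + k <= (int)a.size(); ++i) sa.insert(a.substr(i, k));
  int n = 0;
  for (int i = 0; i + k <= (int)b.size(); ++i)
    if (sa.count(b.substr(i, k))) ++n;
  return n;
}
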