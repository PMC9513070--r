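#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Amino-acid alphabet used throughout: index into the substitution matrix is
// resolved once per call from the matrix dimnames, so any Biostrings-style
// scoring matrix (e.g. BLOSUM62) can be passed straight through.
// Dynamic-programming matrices are flat row-major arrays.

static std::vector<int> encode_seq(const std::string& s,
                                   const std::vector<int>& charmap) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i)
    v[i] = charmap[(unsigned char)s[i]];
  return v;
}

static std::vector<int> build_charmap(const CharacterVector& alpha) {
  std::vector<int> charmap(256, -1);
  for (int i = 0; i < alpha.size(); ++i) {
    std::string a = as<std::string>(alpha[i]);
    if (a.size() == 1) charmap[(unsigned char)a[0]] = i;
  }
  return charmap;
}

struct SubLookup {
  std::vector<int> charmap;
  std::vector<double> sub; // nalpha x nalpha
  int n, xfall;
  SubLookup(const IntegerMatrix& m) {
    CharacterVector alpha = rownames(m);
    charmap = build_charmap(alpha);
    n = alpha.size();
    xfall = 0;
    for (int i = 0; i < n; ++i)
      if (as<std::string>(alpha[i]) == "X") xfall = i;
    sub.resize((size_t)n * n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) sub[(size_t)i * n + j] = m(i, j);
  }
  inline double score(int a, int b) const {
    if (a < 0) a = xfall;
    if (b < 0) b = xfall;
    return sub[(size_t)a * n + b];
  }
};

static const double NEG = -1e18;

// Core global affine NW with traceback; writes identity stats.
static void nw_core(const std::vector<int>& x, const std::vector<int>& y,
                    const SubLookup& S, double gap_open, double gap_ext,
                    double* out_score, int* out_matches, int* out_columns) {
  const int n = x.size(), m = y.size();
  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), Ix((n + 1) * W, NEG),
      Iy((n + 1) * W, NEG);
  std::vector<unsigned char> tM((n + 1) * W, 0), tIx((n + 1) * W, 0),
      tIy((n + 1) * W, 0);
  M[0] = 0;
  for (int i = 1; i <= n; ++i) {
    Ix[i * W] = -gap_open - gap_ext * (i - 1);
    tIx[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[j] = -gap_open - gap_ext * (j - 1);
    tIy[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    const size_t r = i * W, r0 = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const double s = S.score(x[i - 1], y[j - 1]);
      double best = M[r0 + j - 1];
      unsigned char tb = 0;
      if (Ix[r0 + j - 1] > best) { best = Ix[r0 + j - 1]; tb = 1; }
      if (Iy[r0 + j - 1] > best) { best = Iy[r0 + j - 1]; tb = 2; }
      M[r + j] = best + s; tM[r + j] = tb;
      double a0 = M[r0 + j] - gap_open, a1 = Ix[r0 + j] - gap_ext;
      if (a0 >= a1) { Ix[r + j] = a0; tIx[r + j] = 0; }
      else          { Ix[r + j] = a1; tIx[r + j] = 1; }
      double b0 = M[r + j - 1] - gap_open, b1 = Iy[r + j - 1] - gap_ext;
      if (b0 >= b1) { Iy[r + j] = b0; tIy[r + j] = 0; }
      else          { Iy[r + j] = b1; tIy[r + j] = 2; }
    }
  }
  const size_t end = (size_t)n * W + m;
  double score = M[end]; int state = 0;
  if (Ix[end] > score) { score = Ix[end]; state = 1; }
  if (Iy[end] > score) { score = Iy[end]; state = 2; }
  int i = n, j = m, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    ++columns;
    const size_t r = (size_t)i * W;
    if (j == 0 && state == 0) state = 1;
    if (i == 0 && state == 0) state = 2;
    if (state == 0) {
      unsigned char tb = tM[r + j];
      if (x[i - 1] >= 0 && x[i - 1] == y[j - 1]) ++matches;
      --i; --j; state = tb;
    } else if (state == 1) {
      unsigned char tb = tIx[r + j];
      --i; state = tb;
    } else {
      unsigned char tb = tIy[r + j];
      --j; state = tb;
    }
    if (i == 0 && j > 0 && state == 1) state = 2;
    if (j == 0 && i > 0 && state == 2) state = 1;
  }
  *out_score = score; *out_matches = matches; *out_columns = columns;
}

// Needleman-Wunsch, affine gaps, full traceback. Returns percent identity
// with denominator = total alignment columns (gap columns included).
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, IntegerMatrix sub,
                      double gap_open, double gap_ext) {
  SubLookup S(sub);
  std::vector<int> x = encode_seq(a, S.charmap), y = encode_seq(b, S.charmap);
  double score; int matches, columns;
  nw_core(x, y, S, gap_open, gap_ext, &score, &matches, &columns);
  double identity = columns > 0 ? 100.0 * matches / columns : 0.0;
  return List::create(_["identity"] = identity, _["matches"] = matches,
                      _["columns"] = columns, _["score"] = score);
}

// Pairwise percent-identity matrix over a set of sequences.
// [[Rcpp::export]]
NumericMatrix cpp_identity_matrix(CharacterVector seqs, IntegerMatrix sub,
                                  double gap_open, double gap_ext) {
  SubLookup S(sub);
  int n = seqs.size();
  std::vector<std::vector<int>> enc(n);
  for (int i = 0; i < n; ++i)
    enc[i] = encode_seq(as<std::string>(seqs[i]), S.charmap);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) out(i, i) = 100.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double score; int matches, columns;
      nw_core(enc[i], enc[j], S, gap_open, gap_ext, &score, &matches,
              &columns);
      double id = columns > 0 ? 100.0 * matches / columns : 0.0;
      out(i, j) = id; out(j, i) = id;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Smith-Waterman local alignment with affine gaps; reports identity over
// the aligned columns and query coverage (aligned query span / length).
// [[Rcpp::export]]
List cpp_local_align(std::string query, std::string target, IntegerMatrix sub,
                     double gap_open, double gap_ext) {
  SubLookup S(sub);
  std::vector<int> x = encode_seq(query, S.charmap),
      y = encode_seq(target, S.charmap);
  const int n = x.size(), m = y.size();
  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, 0), Ix((n + 1) * W, NEG),
      Iy((n + 1) * W, NEG);
  std::vector<unsigned char> tM((n + 1) * W, 3), tIx((n + 1) * W, 0),
      tIy((n + 1) * W, 0);
  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const size_t r = i * W, r0 = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const double s = S.score(x[i - 1], y[j - 1]);
      double b0 = M[r0 + j - 1];
      unsigned char tb = 0;
      if (Ix[r0 + j - 1] > b0) { b0 = Ix[r0 + j - 1]; tb = 1; }
      if (Iy[r0 + j - 1] > b0) { b0 = Iy[r0 + j - 1]; tb = 2; }
      double v = b0 + s;
      if (v < 0) { v = 0; tb = 3; }
      M[r + j] = v; tM[r + j] = tb;
      double a0 = M[r0 + j] - gap_open, a1 = Ix[r0 + j] - gap_ext;
      if (a0 >= a1) { Ix[r + j] = a0; tIx[r + j] = 0; }
      else          { Ix[r + j] = a1; tIx[r + j] = 1; }
      double c0 = M[r + j - 1] - gap_open, c1 = Iy[r + j - 1] - gap_ext;
      if (c0 >= c1) { Iy[r + j] = c0; tIy[r + j] = 0; }
      else          { Iy[r + j] = c1; tIy[r + j] = 2; }
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, state = 0, matches = 0, columns = 0;
  int qa_end = bi, ta_end = bj, qa_start = bi, ta_start = bj;
  while (i > 0 && j > 0) {
    const size_t r = (size_t)i * W;
    if (state == 0) {
      unsigned char tb = tM[r + j];
      if (tb == 3 && M[r + j] == 0) break;
      ++columns;
      if (x[i - 1] >= 0 && x[i - 1] == y[j - 1]) ++matches;
      qa_start = i; ta_start = j;
      --i; --j;
      if (tb == 3) break;
      state = tb;
    } else if (state == 1) {
      ++columns; unsigned char tb = tIx[r + j]; qa_start = i; --i;
      state = tb;
    } else {
      ++columns; unsigned char tb = tIy[r + j]; ta_start = j; --j;
      state = tb;
    }
  }
  double identity = columns > 0 ? 100.0 * matches / columns : 0.0;
  double qcov = n > 0 ? (double)(qa_end - qa_start + 1) / n : 0.0;
  return List::create(_["score"] = best, _["identity"] = identity,
                      _["matches"] = matches, _["columns"] = columns,
                      _["q_cov"] = qcov,
                      _["t_start"] = ta_start, _["t_end"] = ta_end);
}

// Anchored (ungapped) scan of a position-specific log-odds profile along a
// protein. Terminal overhangs are free; the profile-protein overlap must
// span at least min_overlap columns. Returns the best-scoring offset.
// profile: columns x 20 matrix of bit scores, column order = `alpha`.
// [[Rcpp::export]]
List cpp_profile_scan(std::string protein, NumericMatrix profile,
                      CharacterVector alpha, int min_overlap) {
  std::vector<int> charmap(256, -1);
  for (int i = 0; i < alpha.size(); ++i) {
    std::string a = as<std::string>(alpha[i]);
    charmap[(unsigned char)a[0]] = i;
  }
  const int L = protein.size(), M = profile.nrow(), K = profile.ncol();
  std::vector<double> prof((size_t)M * K);
  for (int c = 0; c < M; ++c)
    for (int a = 0; a < K; ++a) prof[(size_t)c * K + a] = profile(c, a);
  std::vector<int> enc(L);
  for (int i = 0; i < L; ++i) enc[i] = charmap[(unsigned char)protein[i]];
  int minov = min_overlap;
  if (minov > L) minov = L;
  if (minov > M) minov = M;
  double best = R_NegInf; int best_off = 0, best_ov = 0;
  for (int o = -(M - minov); o <= L - minov; ++o) {
    int c0 = std::max(0, -o), c1 = std::min(M, L - o);
    if (c1 - c0 < minov) continue;
    double s = 0;
    for (int c = c0; c < c1; ++c) {
      int a = enc[o + c];
      if (a >= 0) s += prof[(size_t)c * K + a];
    }
    if (s > best) { best = s; best_off = o; best_ov = c1 - c0; }
  }
  return List::create(_["score"] = best, _["offset"] = best_off,
                      _["overlap"] = best_ov);
}

// k-mer prescreen: number of distinct k-mers of each protein found in the
// k-mer set of `reference`. Cheap filter ahead of the full scans.
// [[Rcpp::export]]
IntegerVector cpp_kmer_hits(CharacterVector proteins, std::string reference,
                            int k) {
  std::unordered_set<std::string> ref;
  if ((int)reference.size() >= k)
    for (size_t i = 0; i + k <= reference.size(); ++i)
      ref.insert(reference.substr(i, k));
  int n = proteins.size();
  IntegerVector out(n);
  for (int p = 0; p < n; ++p) {
    std::string s = as<std::string>(proteins[p]);
    int hits = 0;
    if ((int)s.size() >= k) {
      std::unordered_set<std::string> seen;
      for (size_t i = 0; i + k <= s.size(); ++i) {
        std::string km = s.substr(i, k);
        if (ref.count(km) && !seen.count(km)) { ++hits; seen.insert(km); }
      }
    }
    out[p] = hits;
  }
  return out;
}
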