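// Banded global (Needleman-Wunsch-Gotoh) alignment with affine gaps,
// single-linkage clustering over identity links, profile-profile merging
// for consensus building, and a k-mer mismatch scan for primer design.
//
// Scoring convention: a gap of length k costs gap_open + k * gap_ext
// (the same convention Biostrings::pairwiseAlignment uses), so a
// length-1 gap costs gap_open + gap_ext.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -1e30;

struct AlnStats {
  double score;
  int ident;   // identical columns within the non-terminal-gap span
  int kept;    // alignment columns excluding terminal gaps
  int total;   // all alignment columns
};

// Banded Gotoh with full traceback. Band is on the offset j - i, covering
// [min(0, m-n) - w, max(0, m-n) + w]; w large enough makes it exact.
static AlnStats gotoh_banded(const std::string& a, const std::string& b,
                             double match, double mismatch,
                             double gap_open, double gap_ext, int w) {
  const int n = (int)a.size(), m = (int)b.size();
  const int lo = std::min(0, m - n) - w;
  const int hi = std::max(0, m - n) + w;
  const int W = hi - lo + 1;
  const double gop = gap_open + gap_ext;  // cost of opening incl. first base

  std::vector<double> M((size_t)(n + 1) * W, NEG_INF);
  std::vector<double> X((size_t)(n + 1) * W, NEG_INF);  // a_i vs gap
  std::vector<double> Y((size_t)(n + 1) * W, NEG_INF);  // gap vs b_j

  auto idx = [&](int i, int j) { return (size_t)i * W + (j - i - lo); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && (j - i) >= lo && (j - i) <= hi;
  };

  M[idx(0, 0)] = 0.0;
  for (int j = 1; j <= m && inband(0, j); ++j) Y[idx(0, j)] = -(gap_open + j * gap_ext);
  for (int i = 1; i <= n; ++i) {
    if (inband(i, 0)) X[idx(i, 0)] = -(gap_open + i * gap_ext);
    const int jmin = std::max(1, i + lo), jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      const size_t c = idx(i, j);
      // M: diagonal
      if (inband(i - 1, j - 1)) {
        const size_t d = idx(i - 1, j - 1);
        double best = std::max(M[d], std::max(X[d], Y[d]));
        if (best > NEG_INF / 2) {
          double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
          M[c] = best + s;
        }
      }
      // X: consume a_i against a gap
      if (inband(i - 1, j)) {
        const size_t u = idx(i - 1, j);
        X[c] = std::max(M[u] - gop, std::max(X[u] - gap_ext, Y[u] - gop));
      }
      // Y: consume b_j against a gap
      if (inband(i, j - 1)) {
        const size_t l = idx(i, j - 1);
        Y[c] = std::max(M[l] - gop, std::max(Y[l] - gap_ext, X[l] - gop));
      }
    }
  }

  // traceback; state 0 = M, 1 = X, 2 = Y; ties prefer M > X > Y
  int i = n, j = m, state;
  const size_t e = idx(n, m);
  double sc;
  if (M[e] >= X[e] && M[e] >= Y[e]) { state = 0; sc = M[e]; }
  else if (X[e] >= Y[e]) { state = 1; sc = X[e]; }
  else { state = 2; sc = Y[e]; }

  std::vector<char> cols;  // 'I' identical, 'S' substitution, 'G' gap column
  cols.reserve(n + m);
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      cols.push_back(a[i - 1] == b[j - 1] ? 'I' : 'S');
      const size_t d = idx(i - 1, j - 1);
      const double want = M[idx(i, j)] - s;
      if (inband(i - 1, j - 1) && std::abs(M[d] - want) < eps) state = 0;
      else if (inband(i - 1, j - 1) && std::abs(X[d] - want) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      cols.push_back('G');
      const size_t u = idx(i - 1, j);
      const double cur = X[idx(i, j)];
      if (inband(i - 1, j) && std::abs(M[u] - gop - cur) < eps) state = 0;
      else if (inband(i - 1, j) && std::abs(X[u] - gap_ext - cur) < eps) state = 1;
      else state = 2;
      --i;
    } else {
      cols.push_back('G');
      const size_t l = idx(i, j - 1);
      const double cur = Y[idx(i, j)];
      if (inband(i, j - 1) && std::abs(M[l] - gop - cur) < eps) state = 0;
      else if (inband(i, j - 1) && std::abs(Y[l] - gap_ext - cur) < eps) state = 2;
      else state = 1;
      --j;
    }
  }
  std::reverse(cols.begin(), cols.end());

  AlnStats st;
  st.score = sc;
  st.total = (int)cols.size();
  int first = -1, last = -1;
  for (int k = 0; k < (int)cols.size(); ++k)
    if (cols[k] != 'G') { if (first < 0) first = k; last = k; }
  if (first < 0) { st.kept = 0; st.ident = 0; return st; }
  st.kept = last - first + 1;
  st.ident = 0;
  for (int k = first; k <= last; ++k) if (cols[k] == 'I') ++st.ident;
  return st;
}

// [[Rcpp::export]]
List align_stats_cpp(std::string a, std::string b, double match,
                     double mismatch, double gap_open, double gap_ext,
                     int band) {
  int w = band;
  if (w < 0) w = std::max((int)a.size(), (int)b.size());  // exact
  AlnStats st = gotoh_banded(a, b, match, mismatch, gap_open, gap_ext, w);
  return List::create(_["score"] = st.score, _["ident"] = st.ident,
                      _["kept"] = st.kept, _["total"] = st.total);
}

// ---- k-mer machinery -------------------------------------------------------

static bool encode_kmers(const std::string& s, int k,
                         std::vector<uint16_t>& out) {
  out.clear();
  if ((int)s.size() < k) return false;
  uint32_t code = 0, mask = (1u << (2 * k)) - 1u;
  int run = 0;
  for (size_t p = 0; p < s.size(); ++p) {
    int v;
    switch (s[p]) {
      case 'A': case 'a': v = 0; break;
      case 'C': case 'c': v = 1; break;
      case 'G': case 'g': v = 2; break;
      case 'T': case 't': v = 3; break;
      default: v = -1;
    }
    if (v < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)v) & mask;
    if (++run >= k) out.push_back((uint16_t)code);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return !out.empty();
}

static size_t kmer_shared(const std::vector<uint16_t>& A,
                          const std::vector<uint16_t>& B) {
  size_t i = 0, j = 0, shared = 0;
  while (i < A.size() && j < B.size()) {
    if (A[i] == B[j]) { ++shared; ++i; ++j; }
    else if (A[i] < B[j]) ++i;
    else ++j;
  }
  return shared;
}

// ---- single-linkage clustering --------------------------------------------

struct UnionFind {
  std::vector<int> parent, rank_;
  explicit UnionFind(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int x, int y) {
    x = find(x); y = find(y);
    if (x == y) return;
    if (rank_[x] < rank_[y]) std::swap(x, y);
    parent[y] = x;
    if (rank_[x] == rank_[y]) ++rank_[x];
  }
};

// Connected components of the link graph: i ~ j iff score_coverage >= S and
// length_coverage >= L. The k-mer prefilter and the min/max length screen
// are necessary-condition filters only; they cannot drop a true link at the
// identity levels where they are enabled (see the clustering vignette).
// [[Rcpp::export]]
IntegerVector cluster_components_cpp(CharacterVector seqs, double S, double L,
                                     double match, double mismatch,
                                     double gap_open, double gap_ext,
                                     int band_pad, bool use_kmer,
                                     double kmer_frac) {
  const int n = seqs.size();
  std::vector<std::string> sq(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) { sq[i] = as<std::string>(seqs[i]); len[i] = sq[i].size(); }

  std::vector<std::vector<uint16_t>> km(n);
  std::vector<bool> has_km(n, false);
  if (use_kmer)
    for (int i = 0; i < n; ++i) has_km[i] = encode_kmers(sq[i], 8, km[i]);

  UnionFind uf(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (uf.find(i) == uf.find(j)) continue;
      const int lmin = std::min(len[i], len[j]), lmax = std::max(len[i], len[j]);
      // identical columns cannot exceed the shorter length
      if ((double)lmin < S * L * (double)lmax) continue;
      if (use_kmer && has_km[i] && has_km[j]) {
        // a pair linkable at S can differ by at most e_max edits, and one
        // edit (substitution or one-base indel) changes at most 8 distinct
        // 8-mers, so fewer shared 8-mers than min_size - 8 * e_max rules
        // the link out; the fractional screen is the coarser documented one
        const size_t min_sz = std::min(km[i].size(), km[j].size());
        const int e_max = (int)std::ceil((1.0 - S) * (lmax + 8)) + 2;
        const double floor_exact = (double)min_sz - 8.0 * e_max;
        const double floor_frac = kmer_frac * (double)min_sz;
        if ((double)kmer_shared(km[i], km[j]) <
            std::max(floor_frac, floor_exact))
          continue;
      }
      const int w = band_pad < 0 ? lmax : band_pad;
      AlnStats st = gotoh_banded(sq[i], sq[j], match, mismatch, gap_open,
                                 gap_ext, w);
      if (st.kept == 0) continue;
      const double sc = (double)st.ident / (double)st.kept;
      const double lc = (double)st.kept / (double)lmax;
      if (sc >= S && lc >= L) uf.unite(i, j);
    }
  }
  IntegerVector comp(n);
  std::vector<int> relabel(n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (relabel[r] < 0) relabel[r] = next++;
    comp[i] = relabel[r] + 1;  // 1-based
  }
  return comp;
}

// All-pairs identity statistics (used for guide trees and small oracles).
// [[Rcpp::export]]
List identity_matrix_cpp(CharacterVector seqs, double match, double mismatch,
                         double gap_open, double gap_ext, int band) {
  const int n = seqs.size();
  std::vector<std::string> sq(n);
  for (int i = 0; i < n; ++i) sq[i] = as<std::string>(seqs[i]);
  NumericMatrix sc(n, n), lc(n, n);
  for (int i = 0; i < n; ++i) { sc(i, i) = 1.0; lc(i, i) = 1.0; }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const int lmax = std::max(sq[i].size(), sq[j].size());
      const int w = band < 0 ? lmax : band;
      AlnStats st = gotoh_banded(sq[i], sq[j], match, mismatch, gap_open,
                                 gap_ext, w);
      double s = st.kept ? (double)st.ident / st.kept : 0.0;
      double l = (double)st.kept / (double)lmax;
      sc(i, j) = sc(j, i) = s;
      lc(i, j) = lc(j, i) = l;
    }
  }
  return List::create(_["score_coverage"] = sc, _["length_coverage"] = lc);
}

// ---- profile-profile alignment for progressive consensus -------------------

// Profiles are 5 x ncol weighted count matrices (rows A, C, G, T, gap).
// Column score is the expected match/mismatch score over base frequencies;
// existing gap mass is neutral (its cost was paid when it was introduced).
// [[Rcpp::export]]
NumericMatrix profile_align_cpp(NumericMatrix A, NumericMatrix B,
                                double match, double mismatch,
                                double gap_open, double gap_ext) {
  const int nA = A.ncol(), nB = B.ncol();
  double wA = 0.0, wB = 0.0;
  for (int r = 0; r < 5; ++r) { wA += A(r, 0); wB += B(r, 0); }
  const double gop = gap_open + gap_ext;

  auto colscore = [&](int i, int j) {
    double pm = 0.0, occA = 0.0, occB = 0.0;
    for (int r = 0; r < 4; ++r) {
      pm += (A(r, i) / wA) * (B(r, j) / wB);
      occA += A(r, i) / wA;
      occB += B(r, j) / wB;
    }
    const double pmm = occA * occB - pm;  // base-vs-different-base mass
    return pm * match + pmm * mismatch;
  };

  std::vector<double> M((size_t)(nA + 1) * (nB + 1), NEG_INF), X = M, Y = M;
  auto ix = [&](int i, int j) { return (size_t)i * (nB + 1) + j; };
  M[ix(0, 0)] = 0.0;
  for (int i = 1; i <= nA; ++i) X[ix(i, 0)] = -(gap_open + i * gap_ext);
  for (int j = 1; j <= nB; ++j) Y[ix(0, j)] = -(gap_open + j * gap_ext);
  for (int i = 1; i <= nA; ++i) {
    for (int j = 1; j <= nB; ++j) {
      const size_t c = ix(i, j), d = ix(i - 1, j - 1), u = ix(i - 1, j),
                   l = ix(i, j - 1);
      M[c] = std::max(M[d], std::max(X[d], Y[d])) + colscore(i - 1, j - 1);
      X[c] = std::max(M[u] - gop, std::max(X[u] - gap_ext, Y[u] - gop));
      Y[c] = std::max(M[l] - gop, std::max(Y[l] - gap_ext, X[l] - gop));
    }
  }

  // traceback (prefer M > X > Y)
  int i = nA, j = nB, state;
  const size_t e = ix(nA, nB);
  if (M[e] >= X[e] && M[e] >= Y[e]) state = 0;
  else if (X[e] >= Y[e]) state = 1;
  else state = 2;
  std::vector<std::array<double, 5>> cols;
  cols.reserve(nA + nB);
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    std::array<double, 5> col{0, 0, 0, 0, 0};
    if (state == 0) {
      for (int r = 0; r < 5; ++r) col[r] = A(r, i - 1) + B(r, j - 1);
      const double want = M[ix(i, j)] - colscore(i - 1, j - 1);
      const size_t d = ix(i - 1, j - 1);
      if (std::abs(M[d] - want) < eps) state = 0;
      else if (std::abs(X[d] - want) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      for (int r = 0; r < 5; ++r) col[r] = A(r, i - 1);
      col[4] += wB;
      const double cur = X[ix(i, j)];
      const size_t u = ix(i - 1, j);
      if (std::abs(M[u] - gop - cur) < eps) state = 0;
      else if (std::abs(X[u] - gap_ext - cur) < eps) state = 1;
      else state = 2;
      --i;
    } else {
      for (int r = 0; r < 5; ++r) col[r] = B(r, j - 1);
      col[4] += wA;
      const double cur = Y[ix(i, j)];
      const size_t l = ix(i, j - 1);
      if (std::abs(M[l] - gop - cur) < eps) state = 0;
      else if (std::abs(Y[l] - gap_ext - cur) < eps) state = 2;
      else state = 1;
      --j;
    }
    cols.push_back(col);
  }
  std::reverse(cols.begin(), cols.end());
  NumericMatrix out(5, (int)cols.size());
  for (int c = 0; c < (int)cols.size(); ++c)
    for (int r = 0; r < 5; ++r) out(r, c) = cols[c][r];
  return out;
}

// ---- primer design scan ----------------------------------------------------

// For every k-mer of `target`, the minimum Hamming distance to any ungapped
// window of any sequence in `others`, plus the number of those mismatches
// falling in the k-mer's five 3'-terminal positions at the closest window
// (minimised over tied windows).
// [[Rcpp::export]]
IntegerMatrix kmer_cross_mismatch_cpp(std::string target,
                                      CharacterVector others, int k) {
  const int nk = (int)target.size() - k + 1;
  IntegerMatrix out(2, nk);
  for (int s = 0; s < nk; ++s) {
    int best = k + 1, best_end3 = k + 1;
    for (int o = 0; o < others.size(); ++o) {
      const std::string other = as<std::string>(others[o]);
      const int nw = (int)other.size() - k + 1;
      if (nw <= 0) continue;
      for (int t = 0; t < nw; ++t) {
        int mm = 0, e3 = 0;
        for (int p = 0; p < k; ++p) {
          if (target[s + p] != other[t + p]) {
            ++mm;
            if (p >= k - 5) ++e3;
          }
        }
        if (mm < best || (mm == best && e3 < best_end3)) {
          best = mm;
          best_end3 = e3;
        }
      }
    }
    if (best > k) { best = k; best_end3 = 0; }  // no window anywhere
    out(0, s) = best;
    out(1, s) = best_end3;
  }
  return out;
}
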