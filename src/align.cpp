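#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Local affine-gap (Gotoh) alignment with optional banding.
// A gap of length L costs gap_open + L * gap_extend (both arguments negative).
// Banded mode restricts cells to |(j - i) - diag| <= band; full mode (band < 0)
// visits the whole matrix. Traceback is stored per state, so memory is
// O(rows * bandwidth); callers cap full-matrix problem sizes.

static const double NEG_INF = -1e18;

struct AlnResult {
  bool found;
  double score;
  int matches;
  int cols;       // aligned columns incl. internal gaps
  int a_start, a_end, b_start, b_end; // 1-based inclusive, 0 when not found
};

static AlnResult gotoh_local(const std::vector<int>& A, const std::vector<int>& B,
                             const NumericMatrix& S, double go, double ge,
                             int band, int diag) {
  const int m = (int)A.size(), n = (int)B.size();
  const bool full = band < 0;
  const int W = full ? (n + 1) : (2 * band + 1);
  const size_t rows = (size_t)m + 1;

  // score lookup as a flat C array (alphabets are small)
  const int na = S.nrow();
  std::vector<double> Sc((size_t)na * na);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < na; ++j) Sc[(size_t)i * na + j] = S(i, j);

  // rolling value rows (absolute-j indexed); full byte traceback
  std::vector<double> Hprev(n + 2, 0.0), Hcur(n + 2, NEG_INF);
  std::vector<double> Fprev(n + 2, NEG_INF), Fcur(n + 2, NEG_INF);
  std::vector<uint8_t> tbH(rows * W, 0), tbE(rows * W, 0), tbF(rows * W, 0);

  auto col0 = [&](int i) -> long { // absolute j of the row's leftmost slot
    return full ? 0L : (long)i + diag - band;
  };

  double best = 0.0;
  int bi = -1, bj = -1;

  for (int i = 1; i <= m; ++i) {
    int jlo = 1, jhi = n;
    if (!full) {
      jlo = (int)std::max(1L, (long)i + diag - band);
      jhi = (int)std::min((long)n, (long)i + diag + band);
      if (jlo > jhi) {
        // band left the matrix on this row; nothing to compute
        continue;
      }
    }
    uint8_t* rH = &tbH[(size_t)i * W];
    uint8_t* rE = &tbE[(size_t)i * W];
    uint8_t* rF = &tbF[(size_t)i * W];
    const long off = col0(i);
    const double* Srow = &Sc[(size_t)A[i - 1] * na];
    double eprev = NEG_INF;                        // E[i][j-1]
    double hleft = (jlo - 1 == 0) ? 0.0 : NEG_INF; // H[i][j-1]
    for (int j = jlo; j <= jhi; ++j) {
      const size_t k = (size_t)(j - off);
      // E: gap in A (consumes b_j)
      double eh = hleft + go + ge;
      double ee = eprev + ge;
      double e; uint8_t ce;
      if (eh >= ee) { e = eh; ce = 0; } else { e = ee; ce = 1; }
      rE[k] = ce;
      // F: gap in B (consumes a_i); reads previous row at same j
      double up = (i - 1 == 0) ? 0.0 : Hprev[j];
      double fh = up + go + ge;
      double ff = Fprev[j] + ge;
      double f; uint8_t cf;
      if (fh >= ff) { f = fh; cf = 0; } else { f = ff; cf = 1; }
      rF[k] = cf;
      // H: diagonal reads previous row at j-1
      double dg = ((i - 1 == 0 || j - 1 == 0) ? 0.0 : Hprev[j - 1]) +
        Srow[B[j - 1]];
      double h = 0.0; uint8_t c = 0;
      if (dg > h) { h = dg; c = 1; }
      if (e > h) { h = e; c = 2; }
      if (f > h) { h = f; c = 3; }
      rH[k] = c;
      Hcur[j] = h; Fcur[j] = f;
      eprev = e; hleft = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    // seal the banded window edges so the next row reads NEG_INF there
    if (!full) {
      if (jhi + 1 <= n + 1) { Hcur[jhi + 1] = NEG_INF; Fcur[jhi + 1] = NEG_INF; }
      if (jlo - 1 >= 1) { Hcur[jlo - 1] = NEG_INF; Fcur[jlo - 1] = NEG_INF; }
    }
    Hcur[0] = 0.0;
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  AlnResult r{false, 0.0, 0, 0, 0, 0, 0, 0};
  if (bi < 0 || best <= 0.0) return r;
  r.found = true; r.score = best;
  r.a_end = bi; r.b_end = bj;

  auto tb_idx = [&](int i, int j) -> size_t {
    return (size_t)i * W + (size_t)(j - col0(i));
  };
  auto in_band = [&](int i, int j) -> bool {
    if (full) return j >= 0 && j <= n;
    long c = (long)j - col0(i);
    return c >= 0 && c < W && j >= 0 && j <= n;
  };
  int i = bi, j = bj, state = 0; // 0=H,1=E,2=F
  int min_i = bi + 1, min_j = bj + 1;
  while (true) {
    if (i == 0 || j == 0 || !in_band(i, j)) break;
    if (state == 0) {
      uint8_t c = tbH[tb_idx(i, j)];
      if (c == 0) break;
      if (c == 1) {
        r.cols++;
        if (A[i - 1] == B[j - 1]) r.matches++;
        min_i = i; min_j = j;
        --i; --j;
      } else if (c == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      uint8_t c = tbE[tb_idx(i, j)];
      r.cols++; min_j = j; --j;
      state = (c == 0) ? 0 : 1;
    } else {
      uint8_t c = tbF[tb_idx(i, j)];
      r.cols++; min_i = i; --i;
      state = (c == 0) ? 0 : 2;
    }
  }
  r.a_start = min_i; r.b_start = min_j;
  return r;
}

static std::vector<int> encode(const std::string& s,
                               const std::string& alphabet, int other) {
  int map[256];
  for (int i = 0; i < 256; ++i) map[i] = other;
  for (size_t i = 0; i < alphabet.size(); ++i) {
    map[(unsigned char)alphabet[i]] = (int)i;
    map[(unsigned char)std::tolower(alphabet[i])] = (int)i;
  }
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = map[(unsigned char)s[i]];
  return out;
}

static List as_list(const AlnResult& r) {
  return List::create(_["found"] = r.found, _["score"] = r.score,
                      _["matches"] = r.matches, _["cols"] = r.cols,
                      _["a_start"] = r.a_start, _["a_end"] = r.a_end,
                      _["b_start"] = r.b_start, _["b_end"] = r.b_end);
}

// [[Rcpp::export]]
List align_local_cpp(std::string a, std::string b, NumericMatrix score_mat,
                     std::string alphabet, double gap_open, double gap_extend,
                     int band, int diag) {
  int other = (int)alphabet.size() - 1; // last alphabet symbol catches unknowns
  std::vector<int> A = encode(a, alphabet, other);
  std::vector<int> B = encode(b, alphabet, other);
  AlnResult r = gotoh_local(A, B, score_mat, gap_open, gap_extend, band, diag);
  return as_list(r);
}

// All-vs-all alignment of two string sets (full matrix per pair; callers keep
// the sequences short). Returns score/identity/coverage matrices where
// identity = matches/cols and coverage is relative to the shorter sequence.
// [[Rcpp::export]]
List align_all_pairs_cpp(CharacterVector av, CharacterVector bv,
                         NumericMatrix score_mat, std::string alphabet,
                         double gap_open, double gap_extend) {
  int na = av.size(), nb = bv.size();
  int other = (int)alphabet.size() - 1;
  std::vector<std::vector<int>> As(na), Bs(nb);
  for (int i = 0; i < na; ++i) As[i] = encode(as<std::string>(av[i]), alphabet, other);
  for (int j = 0; j < nb; ++j) Bs[j] = encode(as<std::string>(bv[j]), alphabet, other);
  NumericMatrix score(na, nb), ident(na, nb), cover(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      AlnResult r = gotoh_local(As[i], Bs[j], score_mat, gap_open, gap_extend, -1, 0);
      score(i, j) = r.score;
      if (r.found && r.cols > 0) {
        ident(i, j) = (double)r.matches / (double)r.cols;
        int la = (int)As[i].size(), lb = (int)Bs[j].size();
        int shorter = la < lb ? la : lb;
        int span = la < lb ? (r.a_end - r.a_start + 1) : (r.b_end - r.b_start + 1);
        cover(i, j) = (double)span / (double)shorter;
      } else {
        ident(i, j) = 0.0; cover(i, j) = 0.0;
      }
    }
  }
  return List::create(_["score"] = score, _["identity"] = ident,
                      _["coverage"] = cover);
}

// Best shared-k-mer diagonal (diag = j - i, b-position minus a-position).
// Ambiguous bases break words. Words occurring more than max_occ times in
// either sequence are masked (repetitive/low-complexity words otherwise
// dominate the vote table without carrying positional signal). Returns
// (diag, votes); votes == 0 means no shared informative word.
// [[Rcpp::export]]
IntegerVector seed_best_diagonal_cpp(std::string a, std::string b, int k,
                                     int max_occ = 16) {
  auto code = [](char c) -> int {
    switch (c) {
      case 'A': case 'a': return 0;
      case 'C': case 'c': return 1;
      case 'G': case 'g': return 2;
      case 'T': case 't': return 3;
      default: return -1;
    }
  };
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_map<uint64_t, std::vector<int>> pos_a;
  {
    uint64_t w = 0; int run = 0;
    for (int i = 0; i < (int)a.size(); ++i) {
      int c = code(a[i]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto& v = pos_a[w];
        if ((int)v.size() <= max_occ) v.push_back(i - k + 1);
      }
    }
  }
  std::unordered_map<long, long> votes;
  std::unordered_map<uint64_t, int> used_b;
  {
    uint64_t w = 0; int run = 0;
    for (int j = 0; j < (int)b.size(); ++j) {
      int c = code(b[j]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto it = pos_a.find(w);
        if (it != pos_a.end() && (int)it->second.size() <= max_occ &&
            ++used_b[w] <= max_occ) {
          int js = j - k + 1;
          for (int is : it->second) votes[(long)js - is]++;
        }
      }
    }
  }
  long best_diag = 0, best_votes = 0;
  for (auto& kv : votes) {
    if (kv.second > best_votes ||
        (kv.second == best_votes && kv.first < best_diag)) {
      best_diag = kv.first; best_votes = kv.second;
    }
  }
  return IntegerVector::create((int)best_diag, (int)best_votes);
}

static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Bottom-n minhash sketch of the k-mer set (distinct hashed words, the n
// smallest). Two sketches sharing several values indicate k-mer set overlap,
// the cheap candidate filter used before any alignment work.
// [[Rcpp::export]]
NumericVector kmer_sketch_cpp(std::string s, int k = 11, int n = 64) {
  auto code = [](char c) -> int {
    switch (c) {
      case 'A': case 'a': return 0;
      case 'C': case 'c': return 1;
      case 'G': case 'g': return 2;
      case 'T': case 't': return 3;
      default: return -1;
    }
  };
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::set<uint64_t> bottom; // sorted distinct hashes, capped at n
  uint64_t w = 0; int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int c = code(s[i]);
    if (c < 0) { run = 0; w = 0; continue; }
    w = ((w << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      // skip low-complexity words (< 3 distinct bases): they recur across
      // unrelated sequences of similar composition and carry no signal
      int present = 0;
      uint64_t x = w;
      for (int t = 0; t < k; ++t) { present |= 1 << (x & 3ULL); x >>= 2; }
      int distinct = ((present >> 0) & 1) + ((present >> 1) & 1) +
        ((present >> 2) & 1) + ((present >> 3) & 1);
      if (distinct < 3) continue;
      uint64_t h = mix64(w) >> 12; // keep below 2^52: exact as double
      if ((int)bottom.size() < n) bottom.insert(h);
      else if (h < *bottom.rbegin()) {
        bottom.insert(h);
        if ((int)bottom.size() > n) bottom.erase(std::prev(bottom.end()));
      }
    }
  }
  NumericVector out(bottom.size());
  int i = 0;
  for (uint64_t h : bottom) out[i++] = (double)h;
  return out;
}
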