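#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <cstdint>

using namespace Rcpp;

// Global pairwise alignment with linear gap scores, an optional diagonal
// band, and optional free end gaps on either sequence.
//
// Conventions:
//   a: rows (index i, 1..n), b: columns (index j, 1..m)
//   "up"   consumes a base of a against a gap in b
//   "left" consumes a base of b against a gap in a
//   traceback tie order: diagonal > up > left (deterministic)
//
// free_a_start / free_a_end: leading / trailing bases of a may align to
// gaps at no cost (i.e. column-0 / column-m overhangs of a are free).
// free_b_start / free_b_end: same for b.
//
// band: if > 0, only cells with (j - i) within [min(0, m-n) - band,
// max(0, m-n) + band] are computed. band <= 0 means full DP.
//
// Returns list(a = gapped a, b = gapped b, score = optimal score).
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap,
                  int band = -1,
                  bool free_a_start = false, bool free_a_end = false,
                  bool free_b_start = false, bool free_b_end = false) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  int dlo, dhi;
  if (band > 0) {
    dlo = std::min(0, m - n) - band;
    dhi = std::max(0, m - n) + band;
  } else {
    dlo = -n;
    dhi = m;
  }
  if (dlo < -n) dlo = -n;
  if (dhi > m) dhi = m;
  const long long W = (long long)dhi - dlo + 1;
  if ((long long)(n + 1) * W > 600000000LL)
    stop("alignment matrix too large; supply a band");

  // H stored band-relative: cell (i, j) at row i, w = j - i - dlo
  std::vector<double> Hprev((size_t)W, NEG), Hcur((size_t)W, NEG);
  std::vector<uint8_t> TB((size_t)(n + 1) * W, 0);

  auto wix = [&](int i, int j) { return j - i - dlo; };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && (j - i) >= dlo && (j - i) <= dhi;
  };

  // row 0
  for (int j = std::max(0, dlo); j <= std::min(m, dhi); ++j) {
    Hprev[wix(0, j)] = free_b_start ? 0.0 : gap * j;
    if (j > 0) TB[(size_t)0 * W + wix(0, j)] = 3;
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    const int jlo = std::max(0, i + dlo);
    const int jhi = std::min(m, i + dhi);
    for (int j = jlo; j <= jhi; ++j) {
      double best;
      uint8_t tb;
      if (j == 0) {
        best = free_a_start ? 0.0 : gap * i;
        tb = 2;
      } else {
        double sdiag = NEG, sup = NEG, sleft = NEG;
        if (inband(i - 1, j - 1)) {
          double p = Hprev[wix(i - 1, j - 1)];
          if (p > NEG)
            sdiag = p + (a[i - 1] == b[j - 1] ? match : mismatch);
        }
        if (inband(i - 1, j)) {
          double p = Hprev[wix(i - 1, j)];
          if (p > NEG) sup = p + gap;
        }
        if (inband(i, j - 1)) {
          double p = Hcur[wix(i, j - 1)];
          if (p > NEG) sleft = p + gap;
        }
        best = sdiag; tb = 1;
        if (sup > best) { best = sup; tb = 2; }
        if (sleft > best) { best = sleft; tb = 3; }
      }
      Hcur[wix(i, j)] = best;
      TB[(size_t)i * W + wix(i, j)] = tb;
    }
    std::swap(Hprev, Hcur);
    // after swap, Hprev holds row i
    if (i == n) break;
  }
  // Hprev now holds row n (or row 0 if n == 0)
  // To support free ends over the last column we need the full last column,
  // which the band may not retain; recompute end candidates by storing them
  // during the pass is simpler: redo with explicit storage of column m.
  // Instead: we kept only two rows, so re-run cheaply to collect column m.
  // For simplicity and correctness, store column-m scores during the DP.
  // (Handled below by a second pass only if needed.)

  double bestScore;
  int ei = n, ej = m;
  if (!free_a_end && !free_b_end) {
    if (!inband(n, m)) stop("band excludes alignment endpoint");
    bestScore = Hprev[wix(n, m)];
  } else {
    // rerun DP storing column m and row n
    std::vector<double> colm((size_t)n + 1, NEG), rown((size_t)m + 1, NEG);
    std::vector<double> P((size_t)W, NEG), C((size_t)W, NEG);
    for (int j = std::max(0, dlo); j <= std::min(m, dhi); ++j)
      P[wix(0, j)] = free_b_start ? 0.0 : gap * j;
    if (inband(0, m)) colm[0] = P[wix(0, m)];
    if (n == 0) {
      for (int j = std::max(0, dlo); j <= std::min(m, dhi); ++j)
        rown[j] = P[wix(0, j)];
    }
    for (int i = 1; i <= n; ++i) {
      std::fill(C.begin(), C.end(), NEG);
      const int jlo = std::max(0, i + dlo);
      const int jhi = std::min(m, i + dhi);
      for (int j = jlo; j <= jhi; ++j) {
        double best;
        if (j == 0) {
          best = free_a_start ? 0.0 : gap * i;
        } else {
          double sdiag = NEG, sup = NEG, sleft = NEG;
          if (inband(i - 1, j - 1)) {
            double p = P[wix(i - 1, j - 1)];
            if (p > NEG)
              sdiag = p + (a[i - 1] == b[j - 1] ? match : mismatch);
          }
          if (inband(i - 1, j)) {
            double p = P[wix(i - 1, j)];
            if (p > NEG) sup = p + gap;
          }
          if (inband(i, j - 1)) {
            double p = C[wix(i, j - 1)];
            if (p > NEG) sleft = p + gap;
          }
          best = sdiag;
          if (sup > best) best = sup;
          if (sleft > best) best = sleft;
        }
        C[wix(i, j)] = best;
        if (j == m) colm[i] = best;
        if (i == n) rown[j] = best;
      }
      std::swap(P, C);
    }
    bestScore = NEG;
    if (inband(n, m)) { bestScore = colm[n]; ei = n; ej = m; }
    if (free_a_end) {
      // overhang of a below (i, m): prefer larger i on ties
      for (int i = n - 1; i >= 0; --i) {
        if (!inband(i, m)) continue;
        if (colm[i] > bestScore) { bestScore = colm[i]; ei = i; ej = m; }
      }
    }
    if (free_b_end) {
      for (int j = m - 1; j >= 0; --j) {
        if (!inband(n, j)) continue;
        if (rown[j] > bestScore) { bestScore = rown[j]; ei = n; ej = j; }
      }
    }
    if (bestScore == NEG) stop("band excludes all alignment endpoints");
  }

  // traceback
  std::string ga, gb;
  ga.reserve(n + m);
  gb.reserve(n + m);
  // free-end overhangs after the chosen endpoint
  for (int i = n; i > ei; --i) { ga.push_back(a[i - 1]); gb.push_back('-'); }
  for (int j = m; j > ej; --j) { ga.push_back('-'); gb.push_back(b[j - 1]); }
  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    uint8_t tb = TB[(size_t)i * W + wix(i, j)];
    if (tb == 1) {
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]); --i; --j;
    } else if (tb == 2) {
      ga.push_back(a[i - 1]); gb.push_back('-'); --i;
    } else if (tb == 3) {
      ga.push_back('-'); gb.push_back(b[j - 1]); --j;
    } else {
      stop("traceback left the computed band");
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["a"] = ga, _["b"] = gb, _["score"] = bestScore);
}

// Canonicalize indel placement in a gapped pair: slide every gap column
// rightwards through (B,B) match columns of the same base, so equivalent
// placements inside a homopolymer run stack at the run end.
// [[Rcpp::export(name = ".push_gaps_right_cpp")]]
List push_gaps_right_cpp(std::string a, std::string b) {
  const int n = (int)a.size();
  for (int i = n - 2; i >= 0; --i) {
    if (a[i] != '-' && b[i] != '-') continue;
    char B = (a[i] == '-') ? b[i] : a[i];
    int j = i;
    while (j < n - 1 && a[j + 1] == B && b[j + 1] == B) {
      std::swap(a[j], a[j + 1]);
      std::swap(b[j], b[j + 1]);
      ++j;
    }
  }
  return List::create(_["a"] = a, _["b"] = b);
}

// Count of shared distinct k-mers between every pair of sequences,
// used to pick the center sequence of a center-star MSA.
// [[Rcpp::export(name = ".shared_kmer_matrix_cpp")]]
NumericMatrix shared_kmer_matrix_cpp(CharacterVector seqs, int k) {
  const int ns = seqs.size();
  std::vector<std::vector<std::string>> sets(ns);
  for (int s = 0; s < ns; ++s) {
    std::string x = as<std::string>(seqs[s]);
    if ((int)x.size() >= k) {
      std::vector<std::string>& v = sets[s];
      v.reserve(x.size() - k + 1);
      for (size_t p = 0; p + k <= x.size(); ++p) v.push_back(x.substr(p, k));
      std::sort(v.begin(), v.end());
      v.erase(std::unique(v.begin(), v.end()), v.end());
    }
  }
  NumericMatrix out(ns, ns);
  for (int s = 0; s < ns; ++s) {
    for (int t = s + 1; t < ns; ++t) {
      size_t si = 0, ti = 0, shared = 0;
      const std::vector<std::string>& A = sets[s];
      const std::vector<std::string>& B = sets[t];
      while (si < A.size() && ti < B.size()) {
        int c = A[si].compare(B[ti]);
        if (c == 0) { ++shared; ++si; ++ti; }
        else if (c < 0) ++si;
        else ++ti;
      }
      out(s, t) = (double)shared;
      out(t, s) = (double)shared;
    }
  }
  return out;
}
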