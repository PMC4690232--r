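#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels.
//
// Conventions:
//  - scoring: match (>0), mismatch (<0), gap_open (<0), gap_ext (<0);
//    a gap of length L scores gap_open + L * gap_ext.
//  - "D" columns consume a only (gap in b), "I" columns consume b only.
//  - traceback tie preference: match/mismatch > deletion > insertion.

static const double NEG_INF = -1e18;

struct DPResult {
  double score;
  int a_start, a_end, b_start, b_end; // 0-based half-open spans
  std::string ops;                    // one char per column: M/X/D/I
};

// Three-state affine DP. mode 0 = global (Needleman-Wunsch),
// mode 1 = local (Smith-Waterman; local hits start and end on a pair).
static DPResult run_dp(const std::string &a, const std::string &b,
                       double match, double mismatch,
                       double gap_open, double gap_ext, int mode) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  std::vector<double> Mv((size_t)(n + 1) * W, NEG_INF),
      Dv((size_t)(n + 1) * W, NEG_INF), Iv((size_t)(n + 1) * W, NEG_INF);
  // traceback codes: predecessor state 0=M, 1=D, 2=I, 3=fresh start
  std::vector<unsigned char> tbM((size_t)(n + 1) * W, 3),
      tbD((size_t)(n + 1) * W, 0), tbI((size_t)(n + 1) * W, 0);

  Mv[0] = 0.0;
  if (mode == 0) {
    for (int i = 1; i <= n; ++i) { Dv[(size_t)i * W] = gap_open + gap_ext * i; tbD[(size_t)i * W] = 1; }
    for (int j = 1; j <= m; ++j) { Iv[j] = gap_open + gap_ext * j; tbI[j] = 2; }
  }

  double best = NEG_INF;
  int bi = n, bj = m;
  for (int i = 1; i <= n; ++i) {
    const char ca = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t k = (size_t)i * W + j, kd = k - W, ki = k - 1, kdi = k - W - 1;
      const double s = (ca == b[j - 1]) ? match : mismatch;
      // M-state: extend best previous state with a pair (tie: M > D > I)
      double prev = Mv[kdi]; unsigned char t = 0;
      if (Dv[kdi] > prev) { prev = Dv[kdi]; t = 1; }
      if (Iv[kdi] > prev) { prev = Iv[kdi]; t = 2; }
      if (mode == 1 && prev <= 0) { prev = 0.0; t = 3; } // start a new local hit
      Mv[k] = (prev <= NEG_INF / 2) ? NEG_INF : prev + s;
      tbM[k] = t;
      // D-state: open from M/I (tie: M) or extend D
      double od = std::max(Mv[kd], Iv[kd]) + gap_open + gap_ext;
      double ed = Dv[kd] + gap_ext;
      if (od > ed) { Dv[k] = od; tbD[k] = (Mv[kd] >= Iv[kd]) ? 0 : 2; }
      else { Dv[k] = ed; tbD[k] = 1; }
      // I-state
      double oi = std::max(Mv[ki], Dv[ki]) + gap_open + gap_ext;
      double ei = Iv[ki] + gap_ext;
      if (oi > ei) { Iv[k] = oi; tbI[k] = (Mv[ki] >= Dv[ki]) ? 0 : 1; }
      else { Iv[k] = ei; tbI[k] = 2; }
      if (mode == 1 && Mv[k] > best) { best = Mv[k]; bi = i; bj = j; }
    }
  }

  DPResult res;
  int state = 0;
  if (mode == 1) {
    if (best <= 0) {
      res.score = 0; res.a_start = res.a_end = res.b_start = res.b_end = 0;
      return res;
    }
    res.score = best;
  } else {
    const size_t k = (size_t)n * W + m;
    res.score = Mv[k]; state = 0;
    if (Dv[k] > res.score) { res.score = Dv[k]; state = 1; }
    if (Iv[k] > res.score) { res.score = Iv[k]; state = 2; }
    bi = n; bj = m;
  }

  res.a_end = bi; res.b_end = bj;
  std::string rev;
  int i = bi, j = bj;
  while (true) {
    if (i == 0 && j == 0) break;
    if (mode == 1 && (i == 0 || j == 0)) break;
    const size_t k = (size_t)i * W + j;
    if (state == 0) {
      unsigned char t = tbM[k];
      rev.push_back(a[i - 1] == b[j - 1] ? 'M' : 'X');
      --i; --j;
      if (mode == 1 && t == 3) break;
      if (mode == 0 && i == 0 && j == 0) break;
      state = t;
    } else if (state == 1) {
      rev.push_back('D');
      unsigned char t = tbD[k];
      --i;
      state = t;
    } else {
      rev.push_back('I');
      unsigned char t = tbI[k];
      --j;
      state = t;
    }
  }
  res.a_start = i; res.b_start = j;
  res.ops.assign(rev.rbegin(), rev.rend());
  return res;
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b, double match, double mismatch,
                    double gap_open, double gap_ext, bool local) {
  DPResult r = run_dp(a, b, match, mismatch, gap_open, gap_ext, local ? 1 : 0);
  int matches = 0, cols = 0, a_in = 0;
  for (char c : r.ops) {
    ++cols;
    if (c == 'M') { ++matches; ++a_in; }
    else if (c == 'X') ++a_in;
  }
  return List::create(
      _["score"] = r.score, _["ops"] = r.ops,
      _["a_start"] = r.a_start, _["a_end"] = r.a_end,
      _["b_start"] = r.b_start, _["b_end"] = r.b_end,
      _["matches"] = matches, _["columns"] = cols, _["a_aligned"] = a_in);
}

// F[i][j] = best global score aligning a[0..i) vs b[0..j).
static void prefix_matrix(const std::string &a, const std::string &b,
                          double match, double mismatch, double gap_open,
                          double gap_ext, std::vector<double> &F) {
  const int n = (int)a.size(), m = (int)b.size(), W = m + 1;
  std::vector<double> Mv((size_t)(n + 1) * W, NEG_INF),
      Dv((size_t)(n + 1) * W, NEG_INF), Iv((size_t)(n + 1) * W, NEG_INF);
  Mv[0] = 0.0;
  for (int i = 1; i <= n; ++i) Dv[(size_t)i * W] = gap_open + gap_ext * i;
  for (int j = 1; j <= m; ++j) Iv[j] = gap_open + gap_ext * j;
  for (int i = 1; i <= n; ++i) {
    const char ca = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t k = (size_t)i * W + j, kd = k - W, ki = k - 1, kdi = k - W - 1;
      const double s = (ca == b[j - 1]) ? match : mismatch;
      double prev = std::max(Mv[kdi], std::max(Dv[kdi], Iv[kdi]));
      Mv[k] = (prev <= NEG_INF / 2) ? NEG_INF : prev + s;
      Dv[k] = std::max(std::max(Mv[kd], Iv[kd]) + gap_open + gap_ext,
                       Dv[kd] + gap_ext);
      Iv[k] = std::max(std::max(Mv[ki], Dv[ki]) + gap_open + gap_ext,
                       Iv[ki] + gap_ext);
    }
  }
  F.assign((size_t)(n + 1) * W, NEG_INF);
  for (size_t k = 0; k < (size_t)(n + 1) * W; ++k)
    F[k] = std::max(Mv[k], std::max(Dv[k], Iv[k]));
  F[0] = 0.0;
}

// Align-gap-excise split: choose prefix end (i,j) and suffix start (k,l),
// i<=k and j<=l, maximizing
//   global(a[0..i), b[0..j)) + global(a[k..n), b[l..m)),
// excising a[i..k) and b[j..l). Ties: prefix pushed 3' (max i+j, then max j),
// then shortest excision (min k+l given the prefix).
// [[Rcpp::export(name = ".age_split_cpp")]]
List age_split_cpp(std::string a, std::string b, double match, double mismatch,
                   double gap_open, double gap_ext) {
  const int n = (int)a.size(), m = (int)b.size(), W = m + 1;
  std::vector<double> F;
  prefix_matrix(a, b, match, mismatch, gap_open, gap_ext, F);
  std::string ar(a.rbegin(), a.rend()), br(b.rbegin(), b.rend());
  std::vector<double> Brev;
  prefix_matrix(ar, br, match, mismatch, gap_open, gap_ext, Brev);
  // B[k][l] = global score of a[k..n) vs b[l..m) = Brev[n-k][m-l].
  // SM[k][l] = max_{k'>=k, l'>=l} B[k'][l'], argmax preferring smaller k'+l'.
  std::vector<double> SM((size_t)(n + 1) * W, NEG_INF);
  std::vector<int> argK((size_t)(n + 1) * W), argL((size_t)(n + 1) * W);
  for (int k = n; k >= 0; --k) {
    for (int l = m; l >= 0; --l) {
      const size_t idx = (size_t)k * W + l;
      double bestv = Brev[(size_t)(n - k) * W + (m - l)];
      int bk = k, bl = l;
      if (k < n) {
        const size_t d = idx + W;
        if (SM[d] > bestv) { bestv = SM[d]; bk = argK[d]; bl = argL[d]; }
      }
      if (l < m) {
        const size_t r = idx + 1;
        if (SM[r] > bestv) { bestv = SM[r]; bk = argK[r]; bl = argL[r]; }
      }
      SM[idx] = bestv; argK[idx] = bk; argL[idx] = bl;
    }
  }
  double best = NEG_INF;
  int bi = 0, bj = 0;
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      const size_t idx = (size_t)i * W + j;
      if (F[idx] <= NEG_INF / 2) continue;
      const double tot = F[idx] + SM[idx];
      if (tot > best ||
          (tot == best && (i + j > bi + bj || (i + j == bi + bj && j > bj)))) {
        best = tot; bi = i; bj = j;
      }
    }
  }
  const size_t idx = (size_t)bi * W + bj;
  return List::create(_["score"] = best, _["i"] = bi, _["j"] = bj,
                      _["k"] = argK[idx], _["l"] = argL[idx]);
}
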