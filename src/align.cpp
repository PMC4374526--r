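#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP with traceback).
// A gap of length L costs open + ext * (L - 1).
// a, b: 0-based indices into the substitution matrix S.
// local = true: Smith-Waterman (score floored at 0, traceback from the
// maximum cell); local = false: Needleman-Wunsch over the full sequences.
// Returns aligned position vectors (1-based; NA = gap) plus the score.
// [[Rcpp::export(name = ".align_affine")]]
List align_affine(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double open, double ext, bool local) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  const size_t W = (size_t)m + 1;
  std::vector<double> H((size_t)(n + 1) * W, NEG), E(H), F(H);
  // traceback codes -- H: 0 diag, 1 from E, 2 from F, 3 origin/stop
  //                    E: 0 opened from H, 1 extended; F likewise
  std::vector<unsigned char> TH((size_t)(n + 1) * W, 3), TE(TH), TF(TH);

  H[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    double v = -(open + (j - 1) * ext);
    if (local) { H[j] = 0.0; } else { H[j] = v; E[j] = v; TH[j] = 1; TE[j] = 1; }
  }
  for (int i = 1; i <= n; ++i) {
    double v = -(open + (i - 1) * ext);
    size_t r = (size_t)i * W;
    if (local) { H[r] = 0.0; } else { H[r] = v; F[r] = v; TH[r] = 2; TF[r] = 1; }
  }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    size_t r = (size_t)i * W, rp = r - W;
    for (int j = 1; j <= m; ++j) {
      double eo = H[r + j - 1] - open, ee = E[r + j - 1] - ext;
      E[r + j] = (eo >= ee) ? eo : ee;
      TE[r + j] = (eo >= ee) ? 0 : 1;
      double fo = H[rp + j] - open, fe = F[rp + j] - ext;
      F[r + j] = (fo >= fe) ? fo : fe;
      TF[r + j] = (fo >= fe) ? 0 : 1;
      double d = H[rp + j - 1] + S(a[i - 1], b[j - 1]);
      double h = d; unsigned char t = 0;
      if (E[r + j] > h) { h = E[r + j]; t = 1; }
      if (F[r + j] > h) { h = F[r + j]; t = 2; }
      if (local && h < 0.0) { h = 0.0; t = 3; }
      H[r + j] = h; TH[r + j] = t;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }

  int i, j;
  double score;
  if (local) { i = bi; j = bj; score = best; }
  else { i = n; j = m; score = H[(size_t)n * W + m]; }

  std::vector<int> av, bv;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    size_t c = (size_t)i * W + j;
    if (state == 0) {
      unsigned char t = TH[c];
      if (local && (t == 3 || H[c] == 0.0)) break;
      if (t == 0) {
        av.push_back(i); bv.push_back(j); --i; --j;
      } else if (t == 1) state = 1;
      else if (t == 2) state = 2;
      else break;  // global origin
    } else if (state == 1) {           // gap in a, consumes b[j]
      av.push_back(NA_INTEGER); bv.push_back(j);
      state = (TE[c] == 0) ? 0 : 1;
      --j;
    } else {                           // gap in b, consumes a[i]
      av.push_back(i); bv.push_back(NA_INTEGER);
      state = (TF[c] == 0) ? 0 : 2;
      --i;
    }
    if (local && i == 0 && j == 0) break;
  }
  std::reverse(av.begin(), av.end());
  std::reverse(bv.begin(), bv.end());
  return List::create(_["score"] = score,
                      _["a_pos"] = IntegerVector(av.begin(), av.end()),
                      _["b_pos"] = IntegerVector(bv.begin(), bv.end()));
}

// Score-only Smith-Waterman (two rolling rows); used by the windowed
// profiler where tracebacks are never needed and memory matters.
// [[Rcpp::export(name = ".sw_score")]]
double sw_score(IntegerVector a, IntegerVector b, NumericMatrix S,
                double open, double ext) {
  const int n = a.size(), m = b.size();
  std::vector<double> Hp(m + 1, 0.0), H(m + 1, 0.0),
      Ep(m + 1, R_NegInf), E(m + 1, R_NegInf),
      Fp(m + 1, R_NegInf), F(m + 1, R_NegInf);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    H[0] = 0.0; E[0] = R_NegInf; F[0] = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      double e = std::max(H[j - 1] - open, E[j - 1] - ext);
      double f = std::max(Hp[j] - open, Fp[j] - ext);
      double h = Hp[j - 1] + S(a[i - 1], b[j - 1]);
      h = std::max(std::max(h, e), std::max(f, 0.0));
      E[j] = e; F[j] = f; H[j] = h;
      if (h > best) best = h;
    }
    std::swap(H, Hp); std::swap(E, Ep); std::swap(F, Fp);
  }
  return best;
}
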