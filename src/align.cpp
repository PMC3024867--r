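#include <Rcpp.h>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// Global alignment with affine gaps (Gotoh). A gap of length L costs
// gap_open + L * gap_extend (blastp convention: "existence 11, extension 1").
// States: M = residue vs residue, Y = gap in a (b residue consumed),
// X = gap in b (a residue consumed). Ties are broken at fill time with the
// fixed preference M > Y > X, which makes the traceback deterministic and
// prefers match/mismatch over gap-in-a over gap-in-b.

static const double NEG = -1e18;

struct AlnResult {
  double score;
  std::vector<int> pa, pb;  // 0 = gap, else 1-based source position
};

// C(i, j) = score of aligning column i of A against column j of B
// (0-based). Shared DP core for pairwise and profile alignment.
static AlnResult gotoh_core(int n, int m,
                            const std::function<double(int, int)>& C,
                            double gap_open, double gap_extend) {
  double first = gap_open + gap_extend;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix TM(n + 1, m + 1), TX(n + 1, m + 1), TY(n + 1, m + 1);
  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG; X(i, 0) = -(gap_open + i * gap_extend);
    TX(i, 0) = 2;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG; Y(0, j) = -(gap_open + j * gap_extend);
    TY(0, j) = 1;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = C(i - 1, j - 1);
      // predecessor preference M(0) > Y(1) > X(2)
      double m0 = M(i - 1, j - 1), m1 = Y(i - 1, j - 1), m2 = X(i - 1, j - 1);
      if (m0 >= m1 && m0 >= m2)      { M(i, j) = m0 + s; TM(i, j) = 0; }
      else if (m1 >= m2)             { M(i, j) = m1 + s; TM(i, j) = 1; }
      else                           { M(i, j) = m2 + s; TM(i, j) = 2; }
      double y0 = M(i, j - 1) - first, y1 = Y(i, j - 1) - gap_extend,
             y2 = X(i, j - 1) - first;
      if (y0 >= y1 && y0 >= y2)      { Y(i, j) = y0; TY(i, j) = 0; }
      else if (y1 >= y2)             { Y(i, j) = y1; TY(i, j) = 1; }
      else                           { Y(i, j) = y2; TY(i, j) = 2; }
      double x0 = M(i - 1, j) - first, x1 = Y(i - 1, j) - first,
             x2 = X(i - 1, j) - gap_extend;
      if (x0 >= x1 && x0 >= x2)      { X(i, j) = x0; TX(i, j) = 0; }
      else if (x1 >= x2)             { X(i, j) = x1; TX(i, j) = 1; }
      else                           { X(i, j) = x2; TX(i, j) = 2; }
    }
  }
  AlnResult res;
  int state = 0;
  res.score = M(n, m);
  if (Y(n, m) > res.score) { res.score = Y(n, m); state = 1; }
  if (X(n, m) > res.score) { res.score = X(n, m); state = 2; }
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 1;
    else if (j == 0) state = 2;
    if (state == 0) {
      res.pa.push_back(i); res.pb.push_back(j);
      state = TM(i, j); --i; --j;
    } else if (state == 1) {
      res.pa.push_back(0); res.pb.push_back(j);
      state = TY(i, j); --j;
    } else {
      res.pa.push_back(i); res.pb.push_back(0);
      state = TX(i, j); --i;
    }
  }
  std::reverse(res.pa.begin(), res.pa.end());
  std::reverse(res.pb.begin(), res.pb.end());
  return res;
}

// [[Rcpp::plugins(cpp11)]]

// Pairwise alignment; a, b are 0-based indices into S.
// [[Rcpp::export]]
List gotoh_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                     double gap_open, double gap_extend) {
  AlnResult r = gotoh_core(a.size(), b.size(),
                           [&](int i, int j) { return S(a[i], b[j]); },
                           gap_open, gap_extend);
  return List::create(_["score"] = r.score, _["path_a"] = wrap(r.pa),
                      _["path_b"] = wrap(r.pb));
}

// Profile-profile alignment with expected sum-of-pairs column scores.
// A, B: L x K column frequency matrices (gap mass excluded); S: K x K.
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix A, NumericMatrix B, NumericMatrix S,
                       double gap_open, double gap_extend) {
  int n = A.nrow(), m = B.nrow(), K = S.nrow();
  NumericMatrix AS(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) {
      double v = 0;
      for (int l = 0; l < K; ++l) v += A(i, l) * S(l, k);
      AS(i, k) = v;
    }
  NumericMatrix C(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double v = 0;
      for (int k = 0; k < K; ++k) v += AS(i, k) * B(j, k);
      C(i, j) = v;
    }
  AlnResult r = gotoh_core(n, m, [&](int i, int j) { return C(i, j); },
                           gap_open, gap_extend);
  return List::create(_["score"] = r.score, _["path_a"] = wrap(r.pa),
                      _["path_b"] = wrap(r.pb));
}
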