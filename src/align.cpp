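#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh, three-state DP with full traceback).
//
// Gap model: a gap run of length L costs gap_open + L * gap_extend
// (EMBOSS needle convention). End gaps are penalized (true global).
// Traceback tie order: diagonal > up > left, where "up" consumes a
// character of `a` (gap in `b`) and "left" consumes a character of `b`.
// State-internal ties prefer staying aligned (M) over extending a gap.

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 double match, double mismatch,
                 double gap_open, double gap_extend) {
  const int n = (int) a.size();
  const int m = (int) b.size();
  const int W = m + 1;

  std::vector<double> M((n + 1) * W, NEG_INF);
  std::vector<double> X((n + 1) * W, NEG_INF);  // gap in b (vertical, consumes a)
  std::vector<double> Y((n + 1) * W, NEG_INF);  // gap in a (horizontal, consumes b)
  // traceback: which predecessor state fed each cell (0 = M, 1 = X, 2 = Y)
  std::vector<unsigned char> tbM((n + 1) * W, 0), tbX((n + 1) * W, 0), tbY((n + 1) * W, 0);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -gap_open - i * gap_extend;
    tbX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -gap_open - j * gap_extend;
    tbY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = i * W + j;
      const int di = (i - 1) * W + (j - 1);
      const int up = (i - 1) * W + j;
      const int lf = i * W + (j - 1);

      // M: align a[i-1] with b[j-1]; predecessor tie order M > X > Y
      double s = (a[(size_t)(i - 1)] == b[(size_t)(j - 1)]) ? match : mismatch;
      double best = M[di]; unsigned char t = 0;
      if (X[di] > best) { best = X[di]; t = 1; }
      if (Y[di] > best) { best = Y[di]; t = 2; }
      M[ij] = (best <= NEG_INF / 2) ? NEG_INF : best + s;
      tbM[ij] = t;

      // X: gap in b, consume a[i-1]; open from M beats extend on ties
      double openx = (M[up] <= NEG_INF / 2) ? NEG_INF : M[up] - gap_open - gap_extend;
      double extx  = (X[up] <= NEG_INF / 2) ? NEG_INF : X[up] - gap_extend;
      if (openx >= extx) { X[ij] = openx; tbX[ij] = 0; }
      else               { X[ij] = extx;  tbX[ij] = 1; }

      // Y: gap in a, consume b[j-1]
      double openy = (M[lf] <= NEG_INF / 2) ? NEG_INF : M[lf] - gap_open - gap_extend;
      double exty  = (Y[lf] <= NEG_INF / 2) ? NEG_INF : Y[lf] - gap_extend;
      if (openy >= exty) { Y[ij] = openy; tbY[ij] = 0; }
      else               { Y[ij] = exty;  tbY[ij] = 2; }
    }
  }

  const int end = n * W + m;
  double score = M[end]; int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) stop("traceback error in M state");
      unsigned char t = tbM[i * W + j];
      ra.push_back(a[(size_t)(i - 1)]);
      rb.push_back(b[(size_t)(j - 1)]);
      --i; --j; state = t;
    } else if (state == 1) {
      unsigned char t = tbX[i * W + j];
      ra.push_back(a[(size_t)(i - 1)]);
      rb.push_back('-');
      --i; state = t;
    } else {
      unsigned char t = tbY[i * W + j];
      ra.push_back('-');
      rb.push_back(b[(size_t)(j - 1)]);
      --j; state = t;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb, _["score"] = score);
}
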