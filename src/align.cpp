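#include <Rcpp.h>
using namespace Rcpp;

// Global alignment (Needleman-Wunsch with affine gaps, Gotoh three-state DP).
// A gap of length L costs gap_open + L * gap_extend, applied as subtractions.
// Traceback tie-breaking is fixed: prefer the diagonal (match) state, then a
// gap in `b` (consuming `a`, "up"), then a gap in `a` ("left"), so outputs
// are byte-stable across platforms.
//
// ai, bi: 1-based indices of the residues of a and b into the rows/columns of
// the substitution matrix `sub`.

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector ai, IntegerVector bi, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int n = ai.size();
  const int m = bi.size();
  const double NEG = -1e30;
  const int W = m + 1;

  std::vector<double> M((n + 1) * W, NEG), Ix((n + 1) * W, NEG),
      Iy((n + 1) * W, NEG);
  // Traceback pointers: which predecessor state fed each cell.
  // For M: 0=M, 1=Ix, 2=Iy (diagonal step from that state).
  // For Ix: 0=opened from M, 1=extended Ix.  For Iy likewise.
  std::vector<unsigned char> tM((n + 1) * W), tIx((n + 1) * W), tIy((n + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ix[i * W] = -gap_open - i * gap_extend;
    tIx[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[j] = -gap_open - j * gap_extend;
    tIy[j] = (j == 1) ? 0 : 1;
  }

  for (int i = 1; i <= n; ++i) {
    const int r = ai[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j, dg = (i - 1) * W + (j - 1);
      const int up = (i - 1) * W + j, lf = i * W + (j - 1);
      const double s = sub(r, bi[j - 1] - 1);

      // M: diagonal step; prefer M, then Ix, then Iy on ties.
      double best = M[dg]; unsigned char tb = 0;
      if (Ix[dg] > best) { best = Ix[dg]; tb = 1; }
      if (Iy[dg] > best) { best = Iy[dg]; tb = 2; }
      M[idx] = best + s; tM[idx] = tb;

      // Ix: gap in b (consume a).  Prefer opening from M on ties.
      double openx = M[up] - gap_open - gap_extend;
      double extx = Ix[up] - gap_extend;
      if (openx >= extx) { Ix[idx] = openx; tIx[idx] = 0; }
      else               { Ix[idx] = extx;  tIx[idx] = 1; }

      // Iy: gap in a (consume b).
      double openy = M[lf] - gap_open - gap_extend;
      double exty = Iy[lf] - gap_extend;
      if (openy >= exty) { Iy[idx] = openy; tIy[idx] = 0; }
      else               { Iy[idx] = exty;  tIy[idx] = 1; }
    }
  }

  const int end = n * W + m;
  double score = M[end]; int state = 0;
  if (Ix[end] > score) { score = Ix[end]; state = 1; }
  if (Iy[end] > score) { score = Iy[end]; state = 2; }

  // Traceback; ops: 1 = diagonal, 2 = up (gap in b), 3 = left (gap in a).
  std::vector<unsigned char> ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char prev = tM[i * W + j];
      ops.push_back(1); --i; --j; state = prev;
    } else if (state == 1) {
      unsigned char prev = tIx[i * W + j];
      ops.push_back(2); --i; state = (prev == 0) ? 0 : 1;
    } else {
      unsigned char prev = tIy[i * W + j];
      ops.push_back(3); --j; state = (prev == 0) ? 0 : 2;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
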