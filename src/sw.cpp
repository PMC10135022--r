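#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). A gap of length L costs
// open + L * ext. Ties are resolved canonically so the reported identity
// is deterministic: the traceback starts at the first maximal cell in
// row-major order and prefers diagonal > vertical > horizontal moves;
// within a gap state, closing the gap is preferred over extending it.
//
// a, b: 1-based residue indices into the substitution matrix.
// Returns score, number of identical aligned positions, and the
// alignment length (columns, including gaps).

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double open, double ext) {
  int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1), M(n + 1, m + 1), X(n + 1, m + 1),
      Y(n + 1, m + 1);
  const double NEG = -1e100;
  for (int j = 0; j <= m; ++j) { X(0, j) = NEG; Y(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { X(i, 0) = NEG; Y(i, 0) = NEG; }
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      M(i, j) = H(i - 1, j - 1) + s;
      double xo = H(i - 1, j) - open - ext, xc = X(i - 1, j) - ext;
      X(i, j) = xo >= xc ? xo : xc;
      double yo = H(i, j - 1) - open - ext, yc = Y(i, j - 1) - ext;
      Y(i, j) = yo >= yc ? yo : yc;
      double h = 0.0;
      if (M(i, j) > h) h = M(i, j);
      if (X(i, j) > h) h = X(i, j);
      if (Y(i, j) > h) h = Y(i, j);
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["matches"] = 0,
                        _["length"] = 0);
  }
  // traceback
  int i = bi, j = bj, matches = 0, len = 0;
  int state = 0;  // 0 = H, 1 = M, 2 = X, 3 = Y
  while (true) {
    if (state == 0) {
      if (H(i, j) == 0.0) break;
      if (H(i, j) == M(i, j)) state = 1;
      else if (H(i, j) == X(i, j)) state = 2;
      else state = 3;
    } else if (state == 1) {
      ++len;
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
      state = 0;
    } else if (state == 2) {
      ++len;
      bool close = (X(i, j) == H(i - 1, j) - open - ext);
      --i;
      state = close ? 0 : 2;
    } else {
      ++len;
      bool close = (Y(i, j) == H(i, j - 1) - open - ext);
      --j;
      state = close ? 0 : 3;
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["length"] = len);
}
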