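#include <Rcpp.h>
using namespace Rcpp;

// Even-odd (crossing number) point-in-polygon test, vectorised over query
// points. Polygon is given as open vertex lists (first vertex not repeated).
// Points exactly on an edge follow the crossing-number convention; callers
// treat such ties as measure-zero on floating-point pixel grids.
// [[Rcpp::export]]
LogicalVector points_in_polygon(NumericVector x, NumericVector y,
                                NumericVector px, NumericVector py) {
  const int n = x.size();
  const int m = px.size();
  if (py.size() != m) stop("polygon x/y length mismatch");
  LogicalVector inside(n);
  for (int k = 0; k < n; ++k) {
    const double xk = x[k], yk = y[k];
    bool in = false;
    for (int i = 0, j = m - 1; i < m; j = i++) {
      if (((py[i] > yk) != (py[j] > yk)) &&
          (xk < (px[j] - px[i]) * (yk - py[i]) / (py[j] - py[i]) + px[i]))
        in = !in;
    }
    inside[k] = in;
  }
  return inside;
}
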