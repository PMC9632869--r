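#include <Rcpp.h>
using namespace Rcpp;

// Pairwise missing-value dissimilarity D(x, y) = sum_i f(x_i, y_i) with
// f = d^2 / (scale_i + d^2) for observed pairs and the penalty a when
// either coordinate is missing. Returns the full symmetric n x n matrix
// of D values (not the square root used for neighbour queries).
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_dissimilarity(NumericMatrix x,
                                         NumericVector scales,
                                         double penalty) {
  const int n = x.nrow();
  const int p = x.ncol();
  if (scales.size() != p)
    stop("length(scales) must equal ncol(x)");
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int f = 0; f < p; ++f) {
        const double xi = x(i, f);
        const double xj = x(j, f);
        if (ISNAN(xi) || ISNAN(xj)) {
          s += penalty;
        } else {
          const double diff = xi - xj;
          const double sq = diff * diff;
          s += sq / (scales[f] + sq);
        }
      }
      d(i, j) = s;
      d(j, i) = s;
    }
  }
  return d;
}

// Dissimilarities from each row of `query` to each row of `ref`
// (query_rows x ref_rows), same coordinate rule as above.
// [[Rcpp::export]]
NumericMatrix cpp_cross_dissimilarity(NumericMatrix query,
                                      NumericMatrix ref,
                                      NumericVector scales,
                                      double penalty) {
  const int nq = query.nrow();
  const int nr = ref.nrow();
  const int p = query.ncol();
  if (ref.ncol() != p)
    stop("query and ref must have the same number of columns");
  if (scales.size() != p)
    stop("length(scales) must equal the number of columns");
  NumericMatrix d(nq, nr);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nr; ++j) {
      double s = 0.0;
      for (int f = 0; f < p; ++f) {
        const double xi = query(i, f);
        const double xj = ref(j, f);
        if (ISNAN(xi) || ISNAN(xj)) {
          s += penalty;
        } else {
          const double diff = xi - xj;
          const double sq = diff * diff;
          s += sq / (scales[f] + sq);
        }
      }
      d(i, j) = s;
    }
  }
  return d;
}
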