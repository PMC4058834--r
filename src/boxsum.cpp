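#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Sliding-window sum along one dimension of a column-major n1 x n2 x n3
// array, half-extent h, windows truncated at the boundary. Works in place
// via per-line prefix sums.
static void box_pass(std::vector<double> &v, const int n1, const int n2,
                     const int n3, const int dim, const int h) {
  if (h <= 0) return;
  int len, stride, outer_n, outer_step, inner_n, inner_step;
  if (dim == 0) {
    len = n1; stride = 1;
    outer_n = n3; outer_step = n1 * n2; inner_n = n2; inner_step = n1;
  } else if (dim == 1) {
    len = n2; stride = n1;
    outer_n = n3; outer_step = n1 * n2; inner_n = n1; inner_step = 1;
  } else {
    len = n3; stride = n1 * n2;
    outer_n = n2; outer_step = n1; inner_n = n1; inner_step = 1;
  }
  std::vector<double> cs(len + 1);
  for (int a = 0; a < outer_n; ++a) {
    for (int b = 0; b < inner_n; ++b) {
      const int base = a * outer_step + b * inner_step;
      cs[0] = 0.0;
      for (int t = 0; t < len; ++t) cs[t + 1] = cs[t] + v[base + t * stride];
      for (int t = 0; t < len; ++t) {
        int lo = t - h; if (lo < 0) lo = 0;
        int hi = t + h + 1; if (hi > len) hi = len;
        v[base + t * stride] = cs[hi] - cs[lo];
      }
    }
  }
}

// Sum of each 3D sliding window (half-extents h, center included),
// truncated at array boundaries. Separable: one pass per dimension.
// [[Rcpp::export(name = "box_sum3_cpp")]]
NumericVector box_sum3_cpp(NumericVector a, IntegerVector dims, IntegerVector h) {
  if (dims.size() != 3 || h.size() != 3)
    stop("dims and h must have length 3");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  if ((R_xlen_t)n1 * n2 * n3 != a.size()) stop("dims do not match array length");
  std::vector<double> v(a.begin(), a.end());
  box_pass(v, n1, n2, n3, 0, h[0]);
  box_pass(v, n1, n2, n3, 1, h[1]);
  box_pass(v, n1, n2, n3, 2, h[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}
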