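#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// NA-aware median over the third dimension of an n x m x k array.
// Cells that are NA in every slice come back as NA (imputed later per
// metric by the caller).

// [[Rcpp::export(name = ".Call_median_slices")]]
NumericMatrix median_slices(NumericVector cube) {
    IntegerVector dim = cube.attr("dim");
    if (dim.size() != 3) stop("expected a 3-d array");
    const int n = dim[0], m = dim[1], k = dim[2];
    NumericMatrix out(n, m);
    std::vector<double> buf(k);
    const double *x = REAL(cube);
    for (int j = 0; j < m; ++j) {
        for (int i = 0; i < n; ++i) {
            int cnt = 0;
            for (int s = 0; s < k; ++s) {
                double v = x[(size_t)s * n * m + (size_t)j * n + i];
                if (!ISNAN(v)) buf[cnt++] = v;
            }
            if (cnt == 0) {
                out(i, j) = NA_REAL;
            } else if (cnt == 1) {
                out(i, j) = buf[0];
            } else {
                int h = cnt / 2;
                std::nth_element(buf.begin(), buf.begin() + h, buf.begin() + cnt);
                double hi = buf[h];
                if (cnt % 2 == 1) {
                    out(i, j) = hi;
                } else {
                    double lo = *std::max_element(buf.begin(), buf.begin() + h);
                    out(i, j) = (lo + hi) / 2.0;
                }
            }
        }
    }
    return out;
}
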