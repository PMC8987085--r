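#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// centered moving average, truncated window renormalized by actual width
void smooth_trunc(const std::vector<double> &x, std::vector<double> &out,
                  std::vector<double> &cs, int w) {
    const int n = (int)x.size();
    const int left = w / 2, right = w - 1 - left;
    cs.resize(n + 1);
    cs[0] = 0.0;
    for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
    for (int i = 0; i < n; ++i) {
        int lo = std::max(0, i - left);
        int hi = std::min(n - 1, i + right);
        out[i] = (cs[hi + 1] - cs[lo]) / (double)(hi - lo + 1);
    }
}

// maximal contiguous run around the (leftmost) argmax with
// value >= 0.5 * max; returns [lo, hi] inclusive
void main_run(const std::vector<double> &s, int &lo, int &hi) {
    const int n = (int)s.size();
    int apex = 0;
    for (int i = 1; i < n; ++i) if (s[i] > s[apex]) apex = i;
    const double thr = 0.5 * s[apex];
    lo = apex; hi = apex;
    while (lo > 0 && s[lo - 1] >= thr) --lo;
    while (hi < n - 1 && s[hi + 1] >= thr) ++hi;
}

} // namespace

// Permutation null of main-peak bootstrap frequencies.  For each of R
// realizations: ninst random leaf orders of the combined raw measure vector
// v; per order the combination profile is the double moving average of the
// permuted vector (normalization is order-invariant and smoothing is
// linear, so permuting the pre-summed vector is exact); genes falling in
// the main half-height run are counted, and the realization records the
// maximum per-gene frequency over the ninst orders.  Uses R's RNG.

// [[Rcpp::export(name = ".Call_perm_null")]]
NumericVector perm_null(NumericVector v, int R, int ninst, int window) {
    const int m = v.size();
    if (m < 3) stop("need at least 3 genes");
    RNGScope scope;
    NumericVector maxima(R);
    std::vector<double> perm(m), s1(m), s2(m), cs;
    std::vector<int> idx(m), counts(m);
    for (int r = 0; r < R; ++r) {
        std::fill(counts.begin(), counts.end(), 0);
        for (int inst = 0; inst < ninst; ++inst) {
            for (int i = 0; i < m; ++i) idx[i] = i;
            // Fisher-Yates using R's RNG
            for (int i = m - 1; i > 0; --i) {
                int j = (int)(unif_rand() * (i + 1));
                if (j > i) j = i;
                std::swap(idx[i], idx[j]);
            }
            for (int i = 0; i < m; ++i) perm[i] = v[idx[i]];
            smooth_trunc(perm, s1, cs, window);
            smooth_trunc(s1, s2, cs, window);
            int lo, hi;
            main_run(s2, lo, hi);
            for (int p = lo; p <= hi; ++p) ++counts[idx[p]];
        }
        int mx = *std::max_element(counts.begin(), counts.end());
        maxima[r] = (double)mx / (double)ninst;
        if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    return maxima;
}
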