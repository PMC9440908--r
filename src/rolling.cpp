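#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// type-7 quantile of an already-sorted window
static double q7(const std::vector<double>& w, double p) {
    const int m = (int)w.size();
    if (m == 0) return NA_REAL;
    if (m == 1) return w[0];
    double h = (m - 1) * p;
    int lo = (int)std::floor(h);
    if (lo >= m - 1) return w[m - 1];
    return w[lo] + (h - lo) * (w[lo + 1] - w[lo]);
}

// Centered rolling percentile with truncated (shrinking) windows at the
// trace edges. Window for frame i (0-based) is [i-half, i+half] clipped to
// the trace; NA samples are excluded from the window.
// [[Rcpp::export(name = ".run_percentile_cpp")]]
NumericVector run_percentile_cpp(NumericVector x, int half, double prob) {
    const int n = x.size();
    NumericVector out(n);
    std::vector<double> w;
    w.reserve(2 * half + 2);
    // initial window for i = 0: [0, half]
    for (int j = 0; j <= std::min(half, n - 1); ++j)
        if (!ISNAN(x[j]))
            w.insert(std::lower_bound(w.begin(), w.end(), x[j]), x[j]);
    out[0] = q7(w, prob);
    for (int i = 1; i < n; ++i) {
        int add = i + half;
        int drop = i - half - 1;
        if (add < n && !ISNAN(x[add]))
            w.insert(std::lower_bound(w.begin(), w.end(), x[add]), x[add]);
        if (drop >= 0 && !ISNAN(x[drop])) {
            auto it = std::lower_bound(w.begin(), w.end(), x[drop]);
            if (it != w.end()) w.erase(it);
        }
        out[i] = q7(w, prob);
    }
    return out;
}

// 3-D median filter with an axis-aligned cube neighbourhood of radius r,
// clipped at the volume boundary.
// [[Rcpp::export(name = ".median3d_cpp")]]
NumericVector median3d_cpp(NumericVector vol, IntegerVector dim, int r) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericVector out(vol.size());
    std::vector<double> nb;
    nb.reserve((2 * r + 1) * (2 * r + 1) * (2 * r + 1));
    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                nb.clear();
                for (int kk = std::max(0, k - r); kk <= std::min(nz - 1, k + r); ++kk)
                    for (int jj = std::max(0, j - r); jj <= std::min(ny - 1, j + r); ++jj)
                        for (int ii = std::max(0, i - r); ii <= std::min(nx - 1, i + r); ++ii)
                            nb.push_back(vol[ii + nx * (jj + (R_xlen_t)ny * kk)]);
                const size_t m = nb.size();
                std::nth_element(nb.begin(), nb.begin() + m / 2, nb.end());
                double med = nb[m / 2];
                if (m % 2 == 0) {
                    std::nth_element(nb.begin(), nb.begin() + m / 2 - 1,
                                     nb.begin() + m / 2);
                    med = 0.5 * (med + nb[m / 2 - 1]);
                }
                out[i + nx * (j + (R_xlen_t)ny * k)] = med;
            }
        }
    }
    out.attr("dim") = dim;
    return out;
}
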