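#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Interior local extrema; plateaus count once at their midpoint.
static void find_extrema(const double* x, int n,
                         std::vector<int>& mx, std::vector<int>& mn) {
    mx.clear();
    mn.clear();
    int run_start = 0;  // start of the value run ending at i-1
    int dir = 0;
    for (int i = 1; i < n; ++i) {
        if (x[i] == x[i - 1]) continue;
        const int s = (x[i] > x[i - 1]) ? 1 : -1;
        if (dir != 0 && s != dir) {
            const int idx = (run_start + i - 1) / 2;
            if (s < 0) mx.push_back(idx); else mn.push_back(idx);
        }
        dir = s;
        run_start = i;
    }
}

static int count_zero_crossings(const double* x, int n) {
    int c = 0;
    double prev = 0.0;
    for (int i = 0; i < n; ++i) {
        if (x[i] != 0.0) {
            if (prev != 0.0 && ((x[i] > 0.0) != (prev > 0.0))) ++c;
            prev = x[i];
        }
    }
    return c;
}

// Natural cubic spline through (t, y), evaluated at integers 0..n-1 into
// out. Thomas algorithm; linear extrapolation outside the knot span (only
// reachable when mirroring is degenerate).
static void natural_spline_eval(const std::vector<double>& t,
                                const std::vector<double>& y,
                                int n, double* out) {
    const int m = (int)t.size();
    if (m == 1) {
        for (int q = 0; q < n; ++q) out[q] = y[0];
        return;
    }
    if (m == 2) {
        const double sl = (y[1] - y[0]) / (t[1] - t[0]);
        for (int q = 0; q < n; ++q) out[q] = y[0] + sl * (q - t[0]);
        return;
    }
    std::vector<double> h(m - 1), mu(m), z(m), M(m);
    for (int k = 0; k < m - 1; ++k) h[k] = t[k + 1] - t[k];
    mu[0] = 0.0; z[0] = 0.0;
    for (int k = 1; k < m - 1; ++k) {
        const double alpha =
            3.0 * ((y[k + 1] - y[k]) / h[k] - (y[k] - y[k - 1]) / h[k - 1]);
        const double l = 2.0 * (t[k + 1] - t[k - 1]) - h[k - 1] * mu[k - 1];
        mu[k] = h[k] / l;
        z[k] = (alpha - h[k - 1] * z[k - 1]) / l;
    }
    M[m - 1] = 0.0;
    for (int k = m - 2; k >= 0; --k) M[k] = z[k] - mu[k] * M[k + 1];

    int seg = 0;
    for (int q = 0; q < n; ++q) {
        const double xq = (double)q;
        while (seg + 2 < m && t[seg + 1] < xq) ++seg;
        if (xq < t.front()) {
            const double sl = (y[1] - y[0]) / h[0] - h[0] * (2.0 * M[0] + M[1]) / 6.0;
            out[q] = y[0] + sl * (xq - t[0]);
            continue;
        }
        if (xq > t.back()) {
            const double hm = h[m - 2];
            const double sl = (y[m - 1] - y[m - 2]) / hm
                + hm * (M[m - 2] + 2.0 * M[m - 1]) / 6.0;
            out[q] = y[m - 1] + sl * (xq - t[m - 1]);
            continue;
        }
        const double a = t[seg], b = t[seg + 1], hh = b - a;
        const double A = (b - xq) / hh, B = (xq - a) / hh;
        out[q] = A * y[seg] + B * y[seg + 1]
            + ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1])
              * hh * hh / 6.0;
    }
}

// Reusable buffers so sifting does not reallocate n-sized vectors.
struct EmdWorkspace {
    std::vector<int> mx, mn;
    std::vector<double> tu, yu, tl, yl;
    std::vector<double> up, lo, h, hnew;
    explicit EmdWorkspace(int n)
        : up(n), lo(n), h(n), hnew(n) {}
};

// Knot list for one envelope: extrema with up to two per end reflected
// about the first/last sample to tame boundary swings.
static void build_knots(const std::vector<int>& pos, const double* x, int n,
                        std::vector<double>& t, std::vector<double>& y) {
    t.clear(); y.clear();
    const int K = (int)pos.size();
    const int nm = std::min(2, K);
    for (int k = nm - 1; k >= 0; --k) {
        const double p = -(double)pos[k];
        if (p < 0.0) { t.push_back(p); y.push_back(x[pos[k]]); }
    }
    for (int k = 0; k < K; ++k) { t.push_back((double)pos[k]); y.push_back(x[pos[k]]); }
    for (int k = 0; k < nm; ++k) {
        const double p = 2.0 * (n - 1) - (double)pos[K - 1 - k];
        if (p > (double)(n - 1)) { t.push_back(p); y.push_back(x[pos[K - 1 - k]]); }
    }
    size_t w = 1;
    for (size_t k = 1; k < t.size(); ++k) {
        if (t[k] > t[w - 1]) { t[w] = t[k]; y[w] = y[k]; ++w; }
    }
    t.resize(w); y.resize(w);
}

// One IMF by iterated sifting; stop on the Cauchy SD criterion or the sift
// cap. Returns false when the input has too few extrema to sift (caller
// keeps it as residue).
static bool sift_imf(const double* r, int n, double sd_tol, int max_sifts,
                     EmdWorkspace& ws, std::vector<double>& imf) {
    std::copy(r, r + n, ws.h.begin());
    for (int s = 0; s < max_sifts; ++s) {
        find_extrema(ws.h.data(), n, ws.mx, ws.mn);
        if (ws.mx.size() < 2 || ws.mn.size() < 2) {
            if (s == 0) return false;
            break;
        }
        build_knots(ws.mx, ws.h.data(), n, ws.tu, ws.yu);
        build_knots(ws.mn, ws.h.data(), n, ws.tl, ws.yl);
        natural_spline_eval(ws.tu, ws.yu, n, ws.up.data());
        natural_spline_eval(ws.tl, ws.yl, n, ws.lo.data());
        double num = 0.0, den = 0.0;
        for (int q = 0; q < n; ++q) {
            const double em = 0.5 * (ws.up[q] + ws.lo[q]);
            ws.hnew[q] = ws.h[q] - em;
            num += em * em;               // (h - hnew)^2
            den += ws.h[q] * ws.h[q];
        }
        const double sd = (den > 0.0) ? num / den : 0.0;
        ws.h.swap(ws.hnew);
        if (sd < sd_tol) break;
    }
    imf.assign(ws.h.begin(), ws.h.end());
    return true;
}

// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector x, int max_imfs = 8, double sd_tol = 0.2,
             int max_sifts = 50) {
    const int n = x.size();
    std::vector<double> r(x.begin(), x.end());
    std::vector<std::vector<double> > imfs;
    EmdWorkspace ws(n);
    std::vector<double> imf;

    for (int j = 0; j < max_imfs; ++j) {
        find_extrema(r.data(), n, ws.mx, ws.mn);
        if ((int)(ws.mx.size() + ws.mn.size()) < 3) break;
        if (!sift_imf(r.data(), n, sd_tol, max_sifts, ws, imf)) break;
        for (int q = 0; q < n; ++q) r[q] -= imf[q];
        imfs.push_back(imf);
    }

    NumericMatrix M(n, (int)imfs.size());
    for (size_t j = 0; j < imfs.size(); ++j)
        std::copy(imfs[j].begin(), imfs[j].end(), M.begin() + j * n);
    return List::create(_["imfs"] = M,
                        _["residue"] = NumericVector(r.begin(), r.end()));
}

// [[Rcpp::export(name = ".zero_crossings_cpp")]]
int zero_crossings_cpp(NumericVector x) {
    return count_zero_crossings(x.begin(), x.size());
}
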