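#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Separable Gaussian convolution of a 3D array, one pass per axis.
// Kernels are truncated at 4 sigma and renormalised to unit sum.
// edge = 0: zero padding; edge = 1: periodic (wrap-around).

static std::vector<double> gauss_kernel(double sigma) {
    if (sigma <= 0.0) return std::vector<double>(1, 1.0);
    int h = (int)std::ceil(4.0 * sigma);
    std::vector<double> k(2 * h + 1);
    double s = 0.0;
    for (int i = -h; i <= h; ++i) {
        double v = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
        k[i + h] = v;
        s += v;
    }
    for (double &v : k) v /= s;
    return k;
}

static void conv_axis(std::vector<double> &x, int nx, int ny, int nz,
                      int axis, const std::vector<double> &ker, int wrap) {
    int h = ((int)ker.size() - 1) / 2;
    if (h == 0) return;
    int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
    // stride along the axis, and iteration over the complementary plane
    long sx = 1, sy = nx, sz = (long)nx * ny;
    long stride = (axis == 0) ? sx : (axis == 1) ? sy : sz;
    // extended line buffer: [h left pad | n values | h right pad]
    std::vector<double> line(n + 2 * h, 0.0), out(n);
    long n1 = (axis == 0) ? ny : nx;
    long n2 = (axis == 2) ? ny : nz;
    long s1 = (axis == 0) ? sy : sx;
    long s2 = (axis == 2) ? sy : sz;
    for (long i2 = 0; i2 < n2; ++i2) {
        for (long i1 = 0; i1 < n1; ++i1) {
            long base = i1 * s1 + i2 * s2;
            for (int j = 0; j < n; ++j) line[h + j] = x[base + j * stride];
            if (wrap) {
                for (int j = 0; j < h; ++j) {
                    int l = (j - h) % n; if (l < 0) l += n;
                    line[j] = line[h + l];
                    int r = (n + j) % n;
                    line[h + n + j] = line[h + r];
                }
            }
            const double *lp = line.data();
            const double *kp = ker.data();
            int w = 2 * h + 1;
            for (int j = 0; j < n; ++j) {
                double acc = 0.0;
                const double *seg = lp + j;
                for (int t = 0; t < w; ++t) acc += kp[t] * seg[t];
                out[j] = acc;
            }
            for (int j = 0; j < n; ++j) x[base + j * stride] = out[j];
        }
    }
}

// [[Rcpp::export(name = ".gauss_smooth_cpp")]]
NumericVector gauss_smooth_cpp(NumericVector arr, IntegerVector dim,
                               NumericVector sigma, int wrap) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    std::vector<double> x(arr.begin(), arr.end());
    for (int a = 0; a < 3; ++a) {
        std::vector<double> k = gauss_kernel(sigma[a]);
        conv_axis(x, nx, ny, nz, a, k, wrap);
    }
    NumericVector res(x.begin(), x.end());
    res.attr("dim") = dim;
    return res;
}
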