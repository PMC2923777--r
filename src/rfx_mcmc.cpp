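#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Component-wise random-walk Metropolis for the collapsed random-effects
// posterior on (alr(m), log c).  Zero counts contribute nothing to the
// Dirichlet-multinomial sum, so only non-zero cells are visited.  Uses R's
// RNG, so set.seed() in R makes chains reproducible.

struct RfxPost {
    int I, n;
    std::vector<int> nz_i, nz_j;
    std::vector<double> nz_d;
    std::vector<double> k;     // per-subject totals
    int prior_type;            // 0: Dirichlet(pa) on m; 1: Gaussian on alr(m)
    std::vector<double> pa;    // Dirichlet concentrations, or Gaussian means
    double sigma;              // Gaussian prior sd per coordinate
    double lo_u, hi_u;

    RfxPost(const NumericMatrix &d, double lo, double hi)
        : I(d.nrow()), n(d.ncol()), lo_u(lo), hi_u(hi) {
        k.resize(I, 0.0);
        for (int i = 0; i < I; ++i) {
            for (int j = 0; j < n; ++j) {
                double v = d(i, j);
                k[i] += v;
                if (v > 0) {
                    nz_i.push_back(i);
                    nz_j.push_back(j);
                    nz_d.push_back(v);
                }
            }
        }
    }

    // z has length n: n-1 additive-log-ratio coordinates then u = log c
    double operator()(const std::vector<double> &z,
                      std::vector<double> &m) const {
        double u = z[n - 1];
        if (u < lo_u || u > hi_u) return R_NegInf;
        double zmax = 0.0;
        for (int j = 0; j < n - 1; ++j) if (z[j] > zmax) zmax = z[j];
        double denom = std::exp(-zmax);
        for (int j = 0; j < n - 1; ++j) denom += std::exp(z[j] - zmax);
        double ljac = 0.0;
        for (int j = 0; j < n - 1; ++j) {
            m[j] = std::exp(z[j] - zmax) / denom;
            ljac += std::log(m[j]);
        }
        m[n - 1] = std::exp(-zmax) / denom;
        ljac += std::log(m[n - 1]);
        double c = std::exp(u);
        double ll = 0.0;
        for (int i = 0; i < I; ++i) ll += std::lgamma(c) - std::lgamma(c + k[i]);
        for (size_t t = 0; t < nz_d.size(); ++t) {
            double a = c * m[nz_j[t]];
            ll += std::lgamma(a + nz_d[t]) - std::lgamma(a);
        }
        // prior on m, as a density over z (uniform prior on u adds nothing)
        double lprior = 0.0;
        if (prior_type == 1) {
            for (int j = 0; j < n - 1; ++j) {
                double r = z[j] - pa[j];
                lprior += -0.5 * r * r / (sigma * sigma);
            }
            return ll + lprior;   // Gaussian defined on z: no Jacobian
        }
        for (int j = 0; j < n; ++j) lprior += (pa[j] - 1.0) * std::log(m[j]);
        return ll + lprior + ljac;
    }
};

// [[Rcpp::export(name = ".rfx_chain_cpp")]]
List rfx_chain_cpp(NumericMatrix d, NumericVector z0, int iter, int burn_in,
                   int thin, double lo_u, double hi_u, double target_accept,
                   NumericVector prior_par, int prior_type, double sigma) {
    RfxPost post(d, lo_u, hi_u);
    post.pa.assign(prior_par.begin(), prior_par.end());
    post.prior_type = prior_type;
    post.sigma = sigma;
    int n = post.n;
    std::vector<double> z(z0.begin(), z0.end());
    std::vector<double> m(n), m_prop(n);
    std::vector<double> ls(n, std::log(0.5));
    double lp = post(z, m);
    int n_keep = (iter - burn_in) / thin;
    NumericMatrix samples(n_keep, n + 1);
    double acc = 0.0;
    long n_post = 0;
    int row = 0;
    RNGScope scope;
    for (int t = 1; t <= iter; ++t) {
        for (int j = 0; j < n; ++j) {
            double old = z[j];
            // occasional wide step: some marginals (Dirichlet concentration
            // well below 1) have near-flat tails spanning hundreds of log
            // units that a fixed-scale walk cannot traverse
            double wide = (unif_rand() < 0.05) ? 40.0 : 1.0;
            z[j] = old + wide * std::exp(ls[j]) * norm_rand();
            double lpp = post(z, m_prop);
            double a = (lpp > lp) ? 1.0 : std::exp(lpp - lp);
            if (R_finite(lpp) && unif_rand() < a) {
                lp = lpp;
                m = m_prop;
                if (t > burn_in) acc += 1.0;
            } else {
                z[j] = old;
            }
            if (t <= burn_in && wide == 1.0) {
                ls[j] += std::pow((double)t, -0.6) * (a - target_accept);
            }
        }
        if (t > burn_in) {
            n_post += n;
            if ((t - burn_in) % thin == 0 && row < n_keep) {
                for (int j = 0; j < n; ++j) samples(row, j) = m[j];
                samples(row, n) = std::exp(z[n - 1]);
                ++row;
            }
        }
    }
    return List::create(_["samples"] = samples,
                        _["accept_rate"] = n_post > 0 ? acc / n_post : NA_REAL,
                        _["scales"] = NumericVector(ls.begin(), ls.end()));
}
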