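#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Univariate Gaussian mixtures fitted by EM with k-means (Lloyd) initialisation.
// All randomness goes through R's RNG so that set.seed() on the R side makes
// every fit reproducible.

namespace {

const double LOG2PI = 1.837877066409345483560659472811;

// Sample k distinct *values* from x as initial centers; falls back to
// evenly spaced quantiles of the unique values if rejection sampling stalls.
static bool init_centers(const std::vector<double> &x, int k,
                         std::vector<double> &centers) {
    int n = (int)x.size();
    for (int attempt = 0; attempt < 100; ++attempt) {
        centers.clear();
        for (int j = 0; j < k; ++j) {
            int idx = (int)std::floor(unif_rand() * n);
            if (idx >= n) idx = n - 1;
            centers.push_back(x[idx]);
        }
        std::sort(centers.begin(), centers.end());
        bool distinct = true;
        for (int j = 1; j < k; ++j)
            if (centers[j] == centers[j - 1]) { distinct = false; break; }
        if (distinct) return true;
    }
    std::vector<double> u(x);
    std::sort(u.begin(), u.end());
    u.erase(std::unique(u.begin(), u.end()), u.end());
    if ((int)u.size() < k) return false;
    centers.clear();
    for (int j = 0; j < k; ++j) {
        size_t idx = (size_t)std::floor((j + 0.5) / k * u.size());
        if (idx >= u.size()) idx = u.size() - 1;
        centers.push_back(u[idx]);
    }
    std::sort(centers.begin(), centers.end());
    return true;
}

// One-dimensional Lloyd's algorithm; returns within-cluster sum of squares.
static double kmeans1d(const std::vector<double> &x, int k, int max_iter,
                       std::vector<int> &assign, std::vector<double> &centers) {
    int n = (int)x.size();
    assign.assign(n, 0);
    for (int iter = 0; iter < max_iter; ++iter) {
        bool changed = false;
        for (int i = 0; i < n; ++i) {
            int best = 0;
            double bestd = std::abs(x[i] - centers[0]);
            for (int j = 1; j < k; ++j) {
                double d = std::abs(x[i] - centers[j]);
                if (d < bestd) { bestd = d; best = j; }
            }
            if (assign[i] != best) { assign[i] = best; changed = true; }
        }
        std::vector<double> sum(k, 0.0);
        std::vector<int> cnt(k, 0);
        for (int i = 0; i < n; ++i) { sum[assign[i]] += x[i]; cnt[assign[i]]++; }
        for (int j = 0; j < k; ++j) {
            if (cnt[j] == 0) {
                // revive an empty cluster at the point farthest from its center
                int far_i = 0; double far_d = -1.0;
                for (int i = 0; i < n; ++i) {
                    double d = std::abs(x[i] - centers[assign[i]]);
                    if (d > far_d) { far_d = d; far_i = i; }
                }
                centers[j] = x[far_i];
                assign[far_i] = j;
                changed = true;
            } else {
                centers[j] = sum[j] / cnt[j];
            }
        }
        if (!changed && iter > 0) break;
    }
    double wss = 0.0;
    for (int i = 0; i < n; ++i) {
        double d = x[i] - centers[assign[i]];
        wss += d * d;
    }
    return wss;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".gmm_em_cpp")]]
List gmm_em_cpp(NumericVector x_, int k, int n_restarts, int km_max_iter,
                int em_max_iter, double tol, double var_floor) {
    int n = x_.size();
    std::vector<double> x(x_.begin(), x_.end());

    // best-of-restarts k-means initialisation (by within-cluster SS).
    // For large vectors the restarts run on a random subsample and the
    // winning centers are refined by one full-data Lloyd pass; below the
    // threshold the restarts use the full data directly.
    const int sub_n = 1000;
    bool subsample = n > 2 * sub_n;
    std::vector<int> best_assign;
    std::vector<double> best_centers;
    double best_wss = std::numeric_limits<double>::infinity();
    for (int r = 0; r < n_restarts; ++r) {
        std::vector<double> centers;
        std::vector<int> assign;
        double wss;
        if (subsample) {
            std::vector<double> xs(sub_n);
            for (int i = 0; i < sub_n; ++i) {
                int idx = (int)std::floor(unif_rand() * n);
                if (idx >= n) idx = n - 1;
                xs[i] = x[idx];
            }
            if (!init_centers(xs, k, centers)) {
                if (!init_centers(x, k, centers))
                    stop("fewer distinct values than components");
            }
            std::vector<int> sub_assign;
            kmeans1d(xs, k, km_max_iter, sub_assign, centers);
            // score this restart's centers on the full data
            wss = 0.0;
            for (int i = 0; i < n; ++i) {
                double bestd = std::numeric_limits<double>::infinity();
                for (int j = 0; j < k; ++j) {
                    double d = x[i] - centers[j];
                    if (d * d < bestd) bestd = d * d;
                }
                wss += bestd;
            }
        } else {
            if (!init_centers(x, k, centers))
                stop("fewer distinct values than components");
            wss = kmeans1d(x, k, km_max_iter, assign, centers);
        }
        if (wss < best_wss) {
            best_wss = wss;
            best_assign = assign;
            best_centers = centers;
        }
    }
    if (subsample)
        kmeans1d(x, k, km_max_iter, best_assign, best_centers);

    // mixture parameters from the k-means partition
    std::vector<double> w(k), mu(k), v(k);
    {
        std::vector<double> sum(k, 0.0), ss(k, 0.0);
        std::vector<int> cnt(k, 0);
        for (int i = 0; i < n; ++i) { sum[best_assign[i]] += x[i]; cnt[best_assign[i]]++; }
        for (int j = 0; j < k; ++j) mu[j] = cnt[j] > 0 ? sum[j] / cnt[j] : best_centers[j];
        for (int i = 0; i < n; ++i) {
            double d = x[i] - mu[best_assign[i]];
            ss[best_assign[i]] += d * d;
        }
        for (int j = 0; j < k; ++j) {
            w[j] = cnt[j] > 0 ? (double)cnt[j] / n : 1.0 / n;
            v[j] = cnt[j] > 0 ? ss[j] / cnt[j] : var_floor;
            if (v[j] < var_floor) v[j] = var_floor;
        }
        double wsum = 0.0;
        for (int j = 0; j < k; ++j) wsum += w[j];
        for (int j = 0; j < k; ++j) w[j] /= wsum;
    }

    NumericMatrix resp(n, k);
    std::vector<double> trace;
    double loglik = -std::numeric_limits<double>::infinity();
    for (int iter = 0; iter < em_max_iter; ++iter) {
        // E step with log-sum-exp
        double ll = 0.0;
        for (int i = 0; i < n; ++i) {
            double lp[3], m = -std::numeric_limits<double>::infinity();
            for (int j = 0; j < k; ++j) {
                double d = x[i] - mu[j];
                lp[j] = std::log(w[j]) - 0.5 * (LOG2PI + std::log(v[j])) -
                        d * d / (2.0 * v[j]);
                if (lp[j] > m) m = lp[j];
            }
            double s = 0.0;
            for (int j = 0; j < k; ++j) s += std::exp(lp[j] - m);
            double lse = m + std::log(s);
            ll += lse;
            for (int j = 0; j < k; ++j) resp(i, j) = std::exp(lp[j] - lse);
        }
        trace.push_back(ll);
        bool converged = (iter > 0) &&
            (std::abs(ll - loglik) <= tol * (std::abs(loglik) + 1e-12));
        loglik = ll;
        if (converged) break;
        // M step
        for (int j = 0; j < k; ++j) {
            double nj = 0.0, sj = 0.0;
            for (int i = 0; i < n; ++i) { nj += resp(i, j); sj += resp(i, j) * x[i]; }
            if (nj < 1e-12) nj = 1e-12;
            mu[j] = sj / nj;
            double vs = 0.0;
            for (int i = 0; i < n; ++i) {
                double d = x[i] - mu[j];
                vs += resp(i, j) * d * d;
            }
            v[j] = vs / nj;
            if (v[j] < var_floor) v[j] = var_floor;
            w[j] = nj / n;
        }
        double wsum = 0.0;
        for (int j = 0; j < k; ++j) wsum += w[j];
        for (int j = 0; j < k; ++j) w[j] /= wsum;
    }

    // order components by increasing mean for a deterministic labelling
    std::vector<int> ord(k);
    for (int j = 0; j < k; ++j) ord[j] = j;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return mu[a] < mu[b]; });
    NumericVector w_out(k), mu_out(k), v_out(k);
    NumericMatrix resp_out(n, k);
    for (int j = 0; j < k; ++j) {
        w_out[j] = w[ord[j]];
        mu_out[j] = mu[ord[j]];
        v_out[j] = v[ord[j]];
        for (int i = 0; i < n; ++i) resp_out(i, j) = resp(i, ord[j]);
    }

    return List::create(_["weights"] = w_out, _["means"] = mu_out,
                        _["variances"] = v_out, _["loglik"] = loglik,
                        _["trace"] = NumericVector(trace.begin(), trace.end()),
                        _["posterior"] = resp_out);
}
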