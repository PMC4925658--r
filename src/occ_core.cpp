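#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Squared Euclidean distance between row i of A and row j of B.
static inline double sqdist_rows(const NumericMatrix& A, int i,
                                 const NumericMatrix& B, int j) {
    const int d = A.ncol();
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
        const double v = A(i, k) - B(j, k);
        s += v * v;
    }
    return s;
}

// [[Rcpp::export]]
NumericMatrix cpp_rbf_gram(NumericMatrix X, NumericMatrix X2, double gamma) {
    if (X.ncol() != X2.ncol())
        stop("dimension mismatch: %d vs %d columns", X.ncol(), X2.ncol());
    const int n = X.nrow(), m = X2.nrow();
    NumericMatrix K(n, m);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j)
            K(i, j) = std::exp(-gamma * sqdist_rows(X, i, X2, j));
    return K;
}

// SMO (maximal-violating-pair) solver for
//   min 0.5 * a' Q a + p' a   s.t.  sum(a) = 1,  0 <= a_i <= C.
// All "labels" are +1, so the selection rule reduces to picking the
// smallest gradient among indices that can grow and the largest among
// indices that can shrink.
struct SmoResult {
    std::vector<double> alpha;
    std::vector<double> grad;
    int iterations;
    bool converged;
    double objective;
};

static SmoResult smo_core(const NumericMatrix& Q, const std::vector<double>& p,
                          double C, double tol, int max_iter) {
    const int n = Q.nrow();
    SmoResult res;
    res.alpha.assign(n, 1.0 / n);
    res.grad.assign(n, 0.0);
    // G = Q a + p with uniform start
    for (int i = 0; i < n; ++i) {
        double g = p[i];
        for (int j = 0; j < n; ++j) g += Q(i, j) / n;
        res.grad[i] = g;
    }
    res.iterations = 0;
    res.converged = (n == 1);
    const double bound_eps = C * 1e-12;
    for (int it = 0; it < max_iter && n > 1; ++it) {
        int iu = -1, il = -1;
        double gu = std::numeric_limits<double>::infinity();
        double gl = -std::numeric_limits<double>::infinity();
        for (int k = 0; k < n; ++k) {
            if (res.alpha[k] < C - bound_eps && res.grad[k] < gu) {
                gu = res.grad[k]; iu = k;
            }
            if (res.alpha[k] > bound_eps && res.grad[k] > gl) {
                gl = res.grad[k]; il = k;
            }
        }
        if (iu < 0 || il < 0 || gl - gu < tol) {
            res.converged = true;
            res.iterations = it;
            break;
        }
        double denom = Q(iu, iu) + Q(il, il) - 2.0 * Q(iu, il);
        double t = (denom > 1e-300) ? (gl - gu) / denom
                                    : std::numeric_limits<double>::infinity();
        t = std::min(t, C - res.alpha[iu]);
        t = std::min(t, res.alpha[il]);
        res.alpha[iu] += t;
        res.alpha[il] -= t;
        for (int k = 0; k < n; ++k)
            res.grad[k] += t * (Q(k, iu) - Q(k, il));
        res.iterations = it + 1;
    }
    double obj = 0.0;
    for (int i = 0; i < n; ++i)
        obj += 0.5 * res.alpha[i] * (res.grad[i] + p[i]);
    res.objective = obj;
    return res;
}

// [[Rcpp::export]]
List cpp_smo_solve(NumericMatrix Q, NumericVector p, double C, double tol,
                   int max_iter) {
    const int n = Q.nrow();
    if (Q.ncol() != n) stop("Q must be square");
    if (p.size() != n) stop("length(p) must equal nrow(Q)");
    if (C * n < 1.0 - 1e-12)
        stop("infeasible box constraint: C * N < 1");
    std::vector<double> pv(p.begin(), p.end());
    SmoResult r = smo_core(Q, pv, C, tol, max_iter);
    return List::create(_["alpha"] = NumericVector(r.alpha.begin(), r.alpha.end()),
                        _["grad"] = NumericVector(r.grad.begin(), r.grad.end()),
                        _["iterations"] = r.iterations,
                        _["converged"] = r.converged,
                        _["objective"] = r.objective);
}

// Offset rho for the one-class decision function: mean of (K alpha) over
// free support vectors; midpoint of the admissible interval if none.
static double occ_rho(const std::vector<double>& Kalpha,
                      const std::vector<double>& alpha, double C) {
    const int n = (int)alpha.size();
    const double eps = C * 1e-7;
    double s = 0.0; int nf = 0;
    for (int i = 0; i < n; ++i)
        if (alpha[i] > eps && alpha[i] < C - eps) { s += Kalpha[i]; ++nf; }
    if (nf > 0) return s / nf;
    double lo = -std::numeric_limits<double>::infinity();
    double hi = std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
        if (alpha[i] >= C - eps) lo = std::max(lo, Kalpha[i]);  // score <= 0
        if (alpha[i] <= eps)     hi = std::min(hi, Kalpha[i]);  // score >= 0
    }
    if (!std::isfinite(lo)) return hi;
    if (!std::isfinite(hi)) return lo;
    return 0.5 * (lo + hi);
}

// Full leave-pair-out one-class CV with fixed (nu, gamma): for each unit u,
// train on target-class members of all other units (z-scored with the
// training target statistics), then score every subject of unit u.
// gamma <= 0 requests the heuristic 1/n_features. Returns one decision
// score per row (NA if a row's unit is NA).
// [[Rcpp::export]]
NumericVector cpp_occ_cv_scores(NumericMatrix X, IntegerVector unit,
                                LogicalVector is_target, double nu,
                                double gamma, double tol, int max_iter) {
    const int n = X.nrow(), d = X.ncol();
    if (unit.size() != n || is_target.size() != n)
        stop("unit/is_target length mismatch");
    if (nu <= 0.0 || nu > 1.0) stop("nu must be in (0, 1]");
    const double g = (gamma > 0.0) ? gamma : 1.0 / d;
    NumericVector scores(n, NA_REAL);

    std::vector<int> units;
    for (int i = 0; i < n; ++i)
        if (unit[i] != NA_INTEGER) {
            bool seen = false;
            for (size_t k = 0; k < units.size(); ++k)
                if (units[k] == unit[i]) { seen = true; break; }
            if (!seen) units.push_back(unit[i]);
        }
    std::sort(units.begin(), units.end());

    // row-major copy of X for cache-friendly distance loops
    std::vector<double> RX((size_t)n * d);
    for (int i = 0; i < n; ++i)
        for (int k = 0; k < d; ++k)
            RX[(size_t)i * d + k] = X(i, k);

    std::vector<double> ctr(d), scl(d), zt(d);
    for (size_t uu = 0; uu < units.size(); ++uu) {
        const int u = units[uu];
        std::vector<int> tr, te;
        for (int i = 0; i < n; ++i) {
            if (unit[i] == NA_INTEGER) continue;
            if (unit[i] == u) te.push_back(i);
            else if (is_target[i]) tr.push_back(i);
        }
        const int N = (int)tr.size();
        if (N < 1) stop("no target-class training subjects for unit %d", u);
        // training-target standardizer
        for (int k = 0; k < d; ++k) { ctr[k] = 0.0; scl[k] = 1.0; }
        for (int a = 0; a < N; ++a) {
            const double* row = &RX[(size_t)tr[a] * d];
            for (int k = 0; k < d; ++k) ctr[k] += row[k];
        }
        for (int k = 0; k < d; ++k) ctr[k] /= N;
        if (N > 1) {
            std::vector<double> v(d, 0.0);
            for (int a = 0; a < N; ++a) {
                const double* row = &RX[(size_t)tr[a] * d];
                for (int k = 0; k < d; ++k) {
                    const double w = row[k] - ctr[k];
                    v[k] += w * w;
                }
            }
            for (int k = 0; k < d; ++k) {
                const double vv = v[k] / (N - 1);
                scl[k] = (vv > 1e-24) ? std::sqrt(vv) : 1.0;
            }
        }
        std::vector<double> Z((size_t)N * d);
        for (int a = 0; a < N; ++a) {
            const double* row = &RX[(size_t)tr[a] * d];
            double* zr = &Z[(size_t)a * d];
            for (int k = 0; k < d; ++k) zr[k] = (row[k] - ctr[k]) / scl[k];
        }
        NumericMatrix K(N, N);
        for (int a = 0; a < N; ++a) {
            K(a, a) = 1.0;
            const double* za = &Z[(size_t)a * d];
            for (int b = a + 1; b < N; ++b) {
                const double* zb = &Z[(size_t)b * d];
                double q = 0.0;
                for (int k = 0; k < d; ++k) {
                    const double w = za[k] - zb[k];
                    q += w * w;
                }
                const double kv = std::exp(-g * q);
                K(a, b) = kv;
                K(b, a) = kv;
            }
        }
        const double C = 1.0 / (nu * N);
        std::vector<double> p0(N, 0.0);
        SmoResult r = smo_core(K, p0, C, tol, max_iter);
        const double rho = occ_rho(r.grad, r.alpha, C);
        for (size_t b = 0; b < te.size(); ++b) {
            const int i = te[b];
            const double* row = &RX[(size_t)i * d];
            for (int k = 0; k < d; ++k) zt[k] = (row[k] - ctr[k]) / scl[k];
            double s = 0.0;
            for (int a = 0; a < N; ++a) {
                if (r.alpha[a] <= 0.0) continue;
                const double* za = &Z[(size_t)a * d];
                double q = 0.0;
                for (int k = 0; k < d; ++k) {
                    const double w = zt[k] - za[k];
                    q += w * w;
                }
                s += r.alpha[a] * std::exp(-g * q);
            }
            scores[i] = s - rho;
        }
    }
    return scores;
}

// Fixed-point iteration for the RBF preimage of w = sum_i alpha_i phi(x_i):
//   z <- sum_i alpha_i exp(-gamma ||z - x_i||^2) x_i /
//        sum_i alpha_i exp(-gamma ||z - x_i||^2)
// Runs every start in `starts`, accepts steps while the feature-space
// objective sum_i alpha_i k(x_i, z) is non-decreasing (a decrease aborts
// the start, keeping the best pre-decrease iterate), and returns the start
// whose final objective is largest.
// [[Rcpp::export]]
List cpp_preimage(NumericMatrix SV, NumericVector alpha, double gamma,
                  NumericMatrix starts, double tol, int max_iter) {
    const int N = SV.nrow(), d = SV.ncol(), m = starts.nrow();
    if (alpha.size() != N) stop("length(alpha) must equal nrow(SV)");
    if (starts.ncol() != d) stop("starts dimension mismatch");
    if (m < 1) stop("at least one start required");

    NumericVector best_z(d);
    double best_obj = -1.0;
    int best_start = -1, best_iter = 0;
    bool best_conv = false;
    double best_res = NA_REAL;
    LogicalVector conv(m);
    NumericVector objs(m);

    std::vector<double> z(d), znew(d), w(N);
    for (int s = 0; s < m; ++s) {
        for (int k = 0; k < d; ++k) z[k] = starts(s, k);
        double prev_obj = -std::numeric_limits<double>::infinity();
        bool converged = false, aborted = false;
        double resid = NA_REAL;
        int it = 0;
        for (; it < max_iter; ++it) {
            double denom = 0.0, obj = 0.0;
            for (int i = 0; i < N; ++i) {
                double q = 0.0;
                for (int k = 0; k < d; ++k) {
                    const double v = z[k] - SV(i, k);
                    q += v * v;
                }
                w[i] = alpha[i] * std::exp(-gamma * q);
                denom += w[i];
                obj += w[i];
            }
            if (denom < 1e-300) { aborted = true; break; }  // escaped support
            if (obj < prev_obj - 1e-15) { aborted = true; break; }
            prev_obj = obj;
            double step2 = 0.0;
            for (int k = 0; k < d; ++k) {
                double num = 0.0;
                for (int i = 0; i < N; ++i) num += w[i] * SV(i, k);
                znew[k] = num / denom;
                const double dd = znew[k] - z[k];
                step2 += dd * dd;
            }
            resid = std::sqrt(step2);
            for (int k = 0; k < d; ++k) z[k] = znew[k];
            if (resid <= tol) { converged = true; ++it; break; }
        }
        conv[s] = converged;
        objs[s] = prev_obj;
        if (std::isfinite(prev_obj) && prev_obj > best_obj) {
            best_obj = prev_obj;
            for (int k = 0; k < d; ++k) best_z[k] = z[k];
            best_start = s;
            best_iter = it;
            best_conv = converged;
            best_res = resid;
        }
        (void)aborted;
    }
    if (best_start < 0) stop("preimage iteration diverged from every start");
    return List::create(_["z"] = best_z, _["objective"] = best_obj,
                        _["converged"] = best_conv,
                        _["n_iterations"] = best_iter,
                        _["residual"] = best_res,
                        _["start_index"] = best_start + 1,
                        _["start_converged"] = conv,
                        _["start_objectives"] = objs);
}

// Jonker-Volgenant shortest augmenting path solution of the rectangular
// linear assignment problem (nrow <= ncol). Returns, for each row, the
// 1-based column it is assigned to; total cost is minimal.
// [[Rcpp::export]]
IntegerVector cpp_lap_assign(NumericMatrix cost) {
    const int n = cost.nrow(), m = cost.ncol();
    if (n > m) stop("cost matrix must have nrow <= ncol");
    const double INF = std::numeric_limits<double>::infinity();
    std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
    std::vector<int> p(m + 1, 0), way(m + 1, 0);
    for (int i = 1; i <= n; ++i) {
        p[0] = i;
        int j0 = 0;
        std::vector<double> minv(m + 1, INF);
        std::vector<char> used(m + 1, 0);
        do {
            used[j0] = 1;
            const int i0 = p[j0];
            int j1 = -1;
            double delta = INF;
            for (int j = 1; j <= m; ++j) {
                if (used[j]) continue;
                const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
                if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
                if (minv[j] < delta) { delta = minv[j]; j1 = j; }
            }
            for (int j = 0; j <= m; ++j) {
                if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
                else minv[j] -= delta;
            }
            if (j1 < 0) stop("augmenting path search failed");
            j0 = j1;
        } while (p[j0] != 0);
        do {
            const int j1 = way[j0];
            p[j0] = p[j1];
            j0 = j1;
        } while (j0);
    }
    IntegerVector out(n, NA_INTEGER);
    for (int j = 1; j <= m; ++j)
        if (p[j] > 0) out[p[j] - 1] = j;
    return out;
}
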