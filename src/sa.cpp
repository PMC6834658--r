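#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Simulated-annealing core for the minimum-set problem with the
// species-penalty-factor objective:
//   total = sum_i c_i x_i + sum_j SPF_j * H(s_j) * s_j / t_j,
//   s_j = max(0, t_j - offset_j - r_j),  r_j = sum_i x_i a_ij.
// Moves are single-site bit flips with incremental delta evaluation; the
// temperature follows a geometric schedule from t0 to t_final. Uses R's RNG
// stream (seed with set.seed before calling). Returns the best state
// visited, preferring lower penalty among states of equal total (so a
// target-meeting state wins a cost-for-penalty tie, which arises whenever
// SPF_j / t_j equals the unit cost).

static inline double pen1(double t, double off, int r, double spf) {
    if (t <= 0) return 0.0;
    double s = t - off - r;
    return s > 0 ? spf * s / t : 0.0;
}

// [[Rcpp::export]]
List sa_core(IntegerMatrix benefit, NumericVector cost, NumericVector target,
             NumericVector spf, NumericVector rep_offset,
             int iterations, double t0, double t_final) {
    const int m = benefit.nrow(), n = benefit.ncol();
    std::vector< std::vector<int> > adj(m);
    for (int i = 0; i < m; ++i)
        for (int j = 0; j < n; ++j)
            if (benefit(i, j) != 0) adj[i].push_back(j);

    std::vector<int> x(m, 0), r(n, 0);
    double cost_term = 0.0, pen_term = 0.0;
    for (int j = 0; j < n; ++j)
        pen_term += pen1(target[j], rep_offset[j], 0, spf[j]);

    std::vector<int> best_x = x;
    double best_total = cost_term + pen_term, best_pen = pen_term;

    const double ratio = (iterations > 1)
        ? std::pow(t_final / t0, 1.0 / (iterations - 1)) : 1.0;
    double T = t0;

    for (int it = 0; it < iterations; ++it) {
        int i = (int)(unif_rand() * m);
        if (i >= m) i = m - 1;
        const int dir = x[i] ? -1 : 1;
        double dpen = 0.0;
        for (size_t k = 0; k < adj[i].size(); ++k) {
            const int j = adj[i][k];
            dpen += pen1(target[j], rep_offset[j], r[j] + dir, spf[j])
                  - pen1(target[j], rep_offset[j], r[j], spf[j]);
        }
        const double delta = dir * cost[i] + dpen;
        // objective-neutral moves are accepted only when they do not raise
        // the penalty term, so plateau walks drift toward target-meeting
        // states instead of wandering among equal-score infeasible ones
        bool accept;
        if (delta < -1e-12) {
            accept = true;
        } else if (delta <= 1e-12) {
            accept = dpen <= 1e-12;
        } else {
            accept = unif_rand() < std::exp(-delta / T);
        }
        if (accept) {
            x[i] += dir;
            for (size_t k = 0; k < adj[i].size(); ++k) r[adj[i][k]] += dir;
            cost_term += dir * cost[i];
            pen_term += dpen;
            const double cur = cost_term + pen_term;
            if (cur < best_total - 1e-12 ||
                (std::fabs(cur - best_total) <= 1e-12 &&
                 pen_term < best_pen - 1e-12)) {
                best_total = cur;
                best_pen = pen_term;
                best_x = x;
            }
        }
        T *= ratio;
    }
    return List::create(_["x"] = IntegerVector(best_x.begin(), best_x.end()),
                        _["best_total"] = best_total);
}
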