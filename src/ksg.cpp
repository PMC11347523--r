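#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Neighbour counts for the Kraskov-family MI estimator (variant 1).
// For each point i: eps_i is the Chebyshev (max-coordinate) distance to its
// k-th nearest neighbour in the joint (x, y) space (self excluded); nx_i and
// ny_i count the other points whose marginal distance is STRICTLY below
// eps_i. Brute-force O(n^2) scan: exact, cache-friendly, and fast enough for
// the cohort sizes this package targets (n <= a few 10^4).
// [[Rcpp::export(name = ".ksgCounts")]]
List ksgCounts(NumericVector x, NumericVector y, int k) {
    const int n = x.size();
    if (y.size() != n) stop("x and y must have equal length");
    if (k < 1 || k >= n) stop("need 1 <= k < n");
    IntegerVector nx(n), ny(n);
    NumericVector eps(n);
    std::vector<double> d(n);
    for (int i = 0; i < n; ++i) {
        const double xi = x[i], yi = y[i];
        for (int j = 0; j < n; ++j) {
            const double dx = std::fabs(xi - x[j]);
            const double dy = std::fabs(yi - y[j]);
            d[j] = dx > dy ? dx : dy;
        }
        d[i] = R_PosInf;  // exclude self
        std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
        const double e = d[k - 1];
        eps[i] = e;
        int cx = 0, cy = 0;
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            if (std::fabs(xi - x[j]) < e) ++cx;
            if (std::fabs(yi - y[j]) < e) ++cy;
        }
        nx[i] = cx;
        ny[i] = cy;
    }
    return List::create(_["nx"] = nx, _["ny"] = ny, _["eps"] = eps);
}
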