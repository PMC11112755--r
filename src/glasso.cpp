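// Graphical LASSO by block coordinate descent (Friedman-style), with an
// elementwise penalty matrix so block-specific penalties are supported.
// The diagonal of the precision matrix is unpenalized: W_jj = S_jj.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Solves max_Theta log det(Theta) - tr(S Theta) - sum_{j!=k} Lambda_jk |Theta_jk|
// via the dual: each column of the covariance estimate W solves a lasso
// problem; coordinates are updated cyclically with soft-thresholding.
// [[Rcpp::export(name = ".glassoCpp")]]
Rcpp::List glassoCpp(const arma::mat& S, const arma::mat& Lambda,
                     double tol = 1e-6, int maxIter = 200) {
    const int p = S.n_rows;
    arma::mat W = S;                      // working covariance estimate
    arma::mat B(p, p, arma::fill::zeros); // B(k, j): lasso coef of k in col j

    double offAvg = 0.0;
    int cnt = 0;
    for (int i = 0; i < p; ++i)
        for (int j = i + 1; j < p; ++j) { offAvg += std::abs(S(i, j)); ++cnt; }
    if (cnt) offAvg /= cnt;
    if (offAvg < 1e-12) offAvg = 1e-12;
    const double thr = tol * offAvg;

    bool converged = (p == 1);
    int it = 0;
    for (it = 0; it < maxIter && !converged; ++it) {
        double sweepMax = 0.0;
        for (int j = 0; j < p; ++j) {
            // lasso for column j: 0.5 b'W11 b - s12'b + sum Lambda|b|
            for (int inner = 0; inner < 1000; ++inner) {
                double innerMax = 0.0;
                for (int k = 0; k < p; ++k) {
                    if (k == j) continue;
                    double x = S(k, j);
                    for (int l = 0; l < p; ++l) {
                        if (l == j || l == k) continue;
                        x -= W(k, l) * B(l, j);
                    }
                    const double lam = Lambda(k, j);
                    double bNew = 0.0;
                    if (x > lam)       bNew = (x - lam) / W(k, k);
                    else if (x < -lam) bNew = (x + lam) / W(k, k);
                    const double d = std::abs(bNew - B(k, j));
                    if (d > innerMax) innerMax = d;
                    B(k, j) = bNew;
                }
                if (innerMax < thr * 0.1) break;
            }
            // w12 = W11 * beta
            double change = 0.0;
            for (int k = 0; k < p; ++k) {
                if (k == j) continue;
                double w = 0.0;
                for (int l = 0; l < p; ++l) {
                    if (l == j) continue;
                    w += W(k, l) * B(l, j);
                }
                change += std::abs(w - W(k, j));
                W(k, j) = w;
                W(j, k) = w;
            }
            if (p > 1) change /= (p - 1);
            if (change > sweepMax) sweepMax = change;
        }
        if (sweepMax < thr) converged = true;
    }

    // recover Theta from the dual variables
    arma::mat Theta(p, p, arma::fill::zeros);
    for (int j = 0; j < p; ++j) {
        double dot = 0.0;
        for (int k = 0; k < p; ++k)
            if (k != j) dot += W(k, j) * B(k, j);
        const double t22 = 1.0 / (W(j, j) - dot);
        Theta(j, j) = t22;
        for (int k = 0; k < p; ++k)
            if (k != j) Theta(k, j) = -B(k, j) * t22;
    }
    Theta = 0.5 * (Theta + Theta.t());

    // exact-zero support from the lasso coefficients (soft-threshold zeros)
    arma::umat adj(p, p, arma::fill::zeros);
    for (int j = 0; j < p; ++j)
        for (int k = 0; k < p; ++k)
            if (k != j && (B(k, j) != 0.0 || B(j, k) != 0.0))
                adj(k, j) = adj(j, k) = 1;

    return Rcpp::List::create(
        Rcpp::Named("theta") = Theta,
        Rcpp::Named("w") = W,
        Rcpp::Named("adjacency") = adj,
        Rcpp::Named("iterations") = it,
        Rcpp::Named("converged") = converged);
}
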