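// Non-negative least squares for spectral unmixing.
//
// All rows of the data matrix share one design matrix (the basis), so the
// Lawson-Hanson active-set iteration is run on the normal equations with the
// k x k cross-product computed once. k is small (number of basis spectra,
// ~31) which keeps every linear solve cheap.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::mat;
using arma::vec;
using arma::uvec;

// Solve min ||b - A x||^2 s.t. x >= 0 given AtA = A'A and Atb = A'b.
static vec nnls_normal(const mat& AtA, const vec& Atb, double tol)
{
    const arma::uword k = AtA.n_rows;
    vec x(k, arma::fill::zeros);
    std::vector<bool> passive(k, false);
    arma::uword n_passive = 0;

    // outer loop adds at most k variables; inner loop only removes
    const arma::uword max_outer = 3 * k + 30;
    for (arma::uword outer = 0; outer < max_outer; ++outer) {
        vec w = Atb - AtA * x;

        // most violating variable among the active (zero) set
        double wmax = tol;
        arma::sword jmax = -1;
        for (arma::uword j = 0; j < k; ++j) {
            if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
        }
        if (jmax < 0) break;   // KKT satisfied
        passive[jmax] = true;
        ++n_passive;

        for (arma::uword inner = 0; inner < max_outer; ++inner) {
            uvec P(n_passive);
            arma::uword t = 0;
            for (arma::uword j = 0; j < k; ++j) if (passive[j]) P(t++) = j;

            vec z;
            bool ok = arma::solve(z, AtA.submat(P, P), Atb.elem(P),
                                  arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
            if (!ok) z = arma::pinv(AtA.submat(P, P)) * Atb.elem(P);

            if (z.min() > 0.0) {
                x.zeros();
                x.elem(P) = z;
                break;
            }
            // step back along the feasible segment and drop blocking variables
            double alpha = 1.0;
            for (arma::uword t2 = 0; t2 < P.n_elem; ++t2) {
                if (z(t2) <= 0.0) {
                    double xj = x(P(t2));
                    double a = xj / (xj - z(t2));
                    if (a < alpha) alpha = a;
                }
            }
            for (arma::uword t2 = 0; t2 < P.n_elem; ++t2)
                x(P(t2)) += alpha * (z(t2) - x(P(t2)));
            for (arma::uword t2 = 0; t2 < P.n_elem; ++t2) {
                if (x(P(t2)) <= tol * (1.0 + std::abs(z(t2)))) {
                    x(P(t2)) = 0.0;
                    if (passive[P(t2)]) { passive[P(t2)] = false; --n_passive; }
                }
            }
            if (n_passive == 0) break;
        }
    }
    return x;
}

// Row-wise NNLS: each row i of the result minimises ||X_i - w * S||^2, w >= 0.
// X is n x p, S is k x p; the result is n x k.
// [[Rcpp::export]]
arma::mat nnls_rows_cpp(const arma::mat& X, const arma::mat& S)
{
    if (X.n_cols != S.n_cols)
        Rcpp::stop("dimension mismatch: X has %d columns, basis has %d",
                   (int) X.n_cols, (int) S.n_cols);
    const mat AtA = S * S.t();
    const mat SXt = S * X.t();          // k x n
    const double tol = 1e-12 * std::max(1.0, AtA.diag().max());

    mat W(X.n_rows, S.n_rows);
    for (arma::uword i = 0; i < X.n_rows; ++i)
        W.row(i) = nnls_normal(AtA, SXt.col(i), tol).t();
    return W;
}
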