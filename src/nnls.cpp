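#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares:
//   minimize ||A x - b||^2  subject to  x >= 0.
// Written as a compiled kernel because the voxelwise T2 fit calls it tens of
// thousands of times per volume (flip-angle search + regularization search).
//
// Returns x and the squared residual norm. Deterministic: no randomization,
// ties resolved by the first maximal gradient component.
// [[Rcpp::export(name = ".nnls_lh")]]
Rcpp::List nnls_lh(const arma::mat& A, const arma::vec& b) {
    const uword n = A.n_cols;
    if (A.n_rows != b.n_elem)
        Rcpp::stop("nrow(A) must equal length(b)");

    vec x(n, fill::zeros);
    std::vector<bool> passive(n, false);
    uword n_passive = 0;

    const vec Atb = A.t() * b;
    // dual feasibility tolerance, scaled to the problem
    const double tol = 1e-12 * std::max(1.0, norm(Atb, "inf"));

    vec w = Atb; // gradient of 0.5*||Ax-b||^2 at x = 0, negated
    const uword max_outer = 5 * n + 20;

    for (uword outer = 0; outer < max_outer; ++outer) {
        // pick the most violated dual coordinate among the active (zero) set
        sword t = -1;
        double wmax = tol;
        for (uword j = 0; j < n; ++j) {
            if (!passive[j] && w[j] > wmax) { wmax = w[j]; t = (sword)j; }
        }
        if (t < 0) break; // KKT satisfied

        passive[(uword)t] = true;
        ++n_passive;

        // inner loop: unconstrained LS on the passive set, step back to
        // feasibility if any passive coordinate would go non-positive
        for (uword inner = 0; inner < max_outer; ++inner) {
            uvec P(n_passive);
            uword k = 0;
            for (uword j = 0; j < n; ++j) if (passive[j]) P[k++] = j;

            vec z;
            bool ok = solve(z, A.cols(P), b, solve_opts::fast);
            if (!ok) {
                // rank-deficient passive set: fall back to minimum-norm LS
                z = pinv(A.cols(P)) * b;
            }

            if (z.min() > 0) {
                x.zeros();
                x.elem(P) = z;
                break;
            }

            // interpolation step length to the nearest bound
            double alpha = datum::inf;
            for (uword m = 0; m < P.n_elem; ++m) {
                if (z[m] <= 0) {
                    double a = x[P[m]] / (x[P[m]] - z[m]);
                    if (a < alpha) alpha = a;
                }
            }
            for (uword m = 0; m < P.n_elem; ++m)
                x[P[m]] += alpha * (z[m] - x[P[m]]);
            for (uword m = 0; m < P.n_elem; ++m) {
                if (x[P[m]] <= tol * 1e-2 || x[P[m]] <= 0) {
                    x[P[m]] = 0.0;
                    if (passive[P[m]]) { passive[P[m]] = false; --n_passive; }
                }
            }
        }

        w = Atb - A.t() * (A * x);
    }

    const vec r = b - A * x;
    return Rcpp::List::create(Rcpp::Named("x") = x,
                              Rcpp::Named("chi2") = dot(r, r));
}
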