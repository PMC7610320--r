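#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Multiplicative-update NMF for the Gaussian (Frobenius) objective.
//
// The H update uses the current W; the W update uses the freshly updated H.
// After each full iteration the reconstruction R^2 (grand-mean variance
// pooling) is computed and the loop stops when the relative change over the
// last `window` iterations drops below `tol`, or at `max_iter`.
//
// Initial matrices are supplied by the caller (drawn in R under set.seed)
// so that determinism follows R's RNG semantics.
// [[Rcpp::export]]
List nmf_engine(const arma::mat& V, arma::mat W, arma::mat H,
                const int max_iter, const double tol, const int window,
                const double eps) {
    const double gm = arma::accu(V) / static_cast<double>(V.n_elem);
    const double sst = arma::accu(arma::square(V - gm));
    std::vector<double> r2_trace;
    r2_trace.reserve(static_cast<size_t>(max_iter));
    double r2 = 0.0;
    int it = 0;
    for (int i = 1; i <= max_iter; ++i) {
        H %= (W.t() * V) / (W.t() * W * H + eps);
        W %= (V * H.t()) / (W * H * H.t() + eps);
        const double sse = arma::accu(arma::square(V - W * H));
        r2 = 1.0 - sse / sst;
        r2_trace.push_back(r2);
        it = i;
        if (i > window) {
            const double prev = r2_trace[static_cast<size_t>(i - window - 1)];
            if (std::abs(r2 - prev) / std::abs(r2) < tol) break;
        }
    }
    return List::create(_["W"] = W, _["H"] = H, _["R2"] = r2,
                        _["iterations"] = it, _["r2_trace"] = r2_trace);
}
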