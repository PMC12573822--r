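#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for one observation sequence of a
// discrete-time HMM. Emission likelihoods are supplied on the log scale so
// the multivariate Bernoulli product over marks can be computed by matrix
// algebra on the R side; per-row offsets keep exp() in range.
//
// logB: T x K log emission likelihoods  log P(x_t | state k)
// A:    K x K transition matrix (rows sum to 1)
// pi:   K initial distribution
//
// Returns loglik, gamma (T x K posterior state probabilities) and
// xisum (K x K expected transition counts summed over t).
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logB, NumericMatrix A, NumericVector pi) {
    const int T = logB.nrow(), K = logB.ncol();
    if (A.nrow() != K || A.ncol() != K || pi.size() != K)
        stop("dimension mismatch between emissions, transitions and initial distribution");

    NumericMatrix E(T, K);
    std::vector<double> off(T);
    for (int t = 0; t < T; ++t) {
        double m = logB(t, 0);
        for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
        off[t] = m;
        for (int k = 0; k < K; ++k) E(t, k) = std::exp(logB(t, k) - m);
    }

    NumericMatrix alpha(T, K), beta(T, K);
    std::vector<double> c(T);

    double s = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * E(0, k); s += alpha(0, k); }
    if (s <= 0) stop("zero forward probability at t=1");
    c[0] = s;
    for (int k = 0; k < K; ++k) alpha(0, k) /= s;

    for (int t = 1; t < T; ++t) {
        s = 0.0;
        for (int k = 0; k < K; ++k) {
            double a = 0.0;
            for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
            a *= E(t, k);
            alpha(t, k) = a;
            s += a;
        }
        if (s <= 0) stop("zero forward probability");
        c[t] = s;
        for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    }

    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
        for (int k = 0; k < K; ++k) {
            double b = 0.0;
            for (int j = 0; j < K; ++j) b += A(k, j) * E(t + 1, j) * beta(t + 1, j);
            beta(t, k) = b / c[t + 1];
        }
    }

    NumericMatrix gamma(T, K), xisum(K, K);
    for (int t = 0; t < T; ++t) {
        double g = 0.0;
        for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
        for (int k = 0; k < K; ++k) gamma(t, k) /= g;
    }
    for (int t = 0; t + 1 < T; ++t) {
        for (int k = 0; k < K; ++k) {
            const double ak = alpha(t, k);
            if (ak == 0) continue;
            for (int j = 0; j < K; ++j)
                xisum(k, j) += ak * A(k, j) * E(t + 1, j) * beta(t + 1, j) / c[t + 1];
        }
    }

    double ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(c[t]) + off[t];

    return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xisum"] = xisum);
}
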