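#include <Rcpp.h>
using namespace Rcpp;

// Auto-Contractive Map training loop.
//
// Three layers of N units each. An input vector m_s in [0,1]^N is contracted
// into the hidden layer by the vector v, then into the output layer through
// the matrix w; both contractions use the factor (1 - weight / C). Weights
// adapt monotonically toward C, so every (1 - w/C) stays in [0, 1] and the
// system converges when the hidden signal vanishes. Records are presented in
// fixed dataset order each epoch (fully deterministic).
//
// [[Rcpp::export]]
List autocm_train_cpp(NumericMatrix X, double C, double lr, int max_epochs,
                      double tol, double init) {
  const int R = X.nrow(), N = X.ncol();
  NumericVector v(N, init);
  NumericMatrix w(N, N);
  std::fill(w.begin(), w.end(), init);
  std::vector<double> trace;
  trace.reserve(64);
  bool converged = false;
  int epoch = 0;

  std::vector<double> mh(N), net(N), mt(N);
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    double delta_sum = 0.0;
    for (int r = 0; r < R; ++r) {
      // input -> hidden contraction and adaptation of v
      for (int i = 0; i < N; ++i) {
        double ms = X(r, i);
        double ci = 1.0 - v[i] / C;
        mh[i] = ms * ci;
        double dv = lr * (ms - mh[i]) * ci;
        v[i] += dv;
        delta_sum += std::fabs(dv);
      }
      // hidden -> output contraction through w and adaptation of w
      for (int i = 0; i < N; ++i) {
        double s = 0.0;
        for (int j = 0; j < N; ++j) s += mh[j] * (1.0 - w(i, j) / C);
        net[i] = s;
        mt[i] = mh[i] * (1.0 - net[i] / C);
      }
      for (int i = 0; i < N; ++i) {
        double diff = mh[i] - mt[i];
        if (diff == 0.0) continue;
        for (int j = 0; j < N; ++j) {
          double dw = lr * diff * (1.0 - w(i, j) / C) * mh[j];
          w(i, j) += dw;
          delta_sum += std::fabs(dw);
        }
      }
      if (!std::isfinite(delta_sum)) {
        stop("Non-finite weight update at epoch %d, record %d.", epoch, r + 1);
      }
    }
    double mean_delta = delta_sum / (double)(R * (N + (long long)N * N));
    trace.push_back(mean_delta);
    if (mean_delta < tol) { converged = true; break; }
  }
  if (epoch > max_epochs) epoch = max_epochs;

  return List::create(_["v"] = v, _["w"] = w,
                      _["epochs_run"] = epoch,
                      _["converged"] = converged,
                      _["training_trace"] = NumericVector(trace.begin(), trace.end()));
}
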