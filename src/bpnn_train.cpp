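#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

// Deterministic PRNG (splitmix64) so training is reproducible from
// rng_seed alone, independent of R's RNG state.
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(unif() * n) % n; }
};

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Online (per-sample) gradient-descent back-propagation for a three-layer
// sigmoid network with MSE loss. X: n x ni (rows already normalized to
// [0,1]); T: n x no one-hot targets. Weights initialized uniform in
// [-0.5, 0.5]; sample order shuffled each epoch (Fisher-Yates); stops when
// the epoch-mean MSE (mean over samples and output units of squared error,
// measured before each sample's update) drops below tol.
// [[Rcpp::export]]
Rcpp::List bpnn_train_cpp(Rcpp::NumericMatrix X, Rcpp::NumericMatrix T,
                          int nh, double lr, double tol, int max_epochs,
                          double seed) {
  const int n = X.nrow(), ni = X.ncol(), no = T.ncol();
  SplitMix64 rng((uint64_t)seed);

  std::vector<double> W1((size_t)nh * ni), b1(nh);
  std::vector<double> W2((size_t)no * nh), b2(no);
  for (auto &w : W1) w = rng.unif() - 0.5;
  for (auto &w : b1) w = rng.unif() - 0.5;
  for (auto &w : W2) w = rng.unif() - 0.5;
  for (auto &w : b2) w = rng.unif() - 0.5;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> h(nh), o(no), dout(no), dhid(nh);
  std::vector<double> mse_hist;
  mse_hist.reserve(max_epochs);
  bool converged = false;
  int epochs = 0;

  for (int ep = 0; ep < max_epochs; ++ep) {
    for (int i = n - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(order[i], order[j]);
    }
    double sse = 0.0;
    for (int s = 0; s < n; ++s) {
      const int r = order[s];
      for (int j = 0; j < nh; ++j) {
        double z = b1[j];
        for (int i = 0; i < ni; ++i) z += W1[(size_t)j * ni + i] * X(r, i);
        h[j] = sigmoid(z);
      }
      for (int k = 0; k < no; ++k) {
        double z = b2[k];
        for (int j = 0; j < nh; ++j) z += W2[(size_t)k * nh + j] * h[j];
        o[k] = sigmoid(z);
        const double e = o[k] - T(r, k);
        sse += e * e;
        dout[k] = e * o[k] * (1.0 - o[k]);
      }
      for (int j = 0; j < nh; ++j) {
        double acc = 0.0;
        for (int k = 0; k < no; ++k) acc += W2[(size_t)k * nh + j] * dout[k];
        dhid[j] = acc * h[j] * (1.0 - h[j]);
      }
      for (int k = 0; k < no; ++k) {
        const double d = lr * dout[k];
        for (int j = 0; j < nh; ++j) W2[(size_t)k * nh + j] -= d * h[j];
        b2[k] -= d;
      }
      for (int j = 0; j < nh; ++j) {
        const double d = lr * dhid[j];
        for (int i = 0; i < ni; ++i) W1[(size_t)j * ni + i] -= d * X(r, i);
        b1[j] -= d;
      }
    }
    const double mse = sse / ((double)n * no);
    mse_hist.push_back(mse);
    epochs = ep + 1;
    if (mse < tol) { converged = true; break; }
  }

  Rcpp::NumericMatrix W1m(nh, ni), W2m(no, nh);
  for (int j = 0; j < nh; ++j)
    for (int i = 0; i < ni; ++i) W1m(j, i) = W1[(size_t)j * ni + i];
  for (int k = 0; k < no; ++k)
    for (int j = 0; j < nh; ++j) W2m(k, j) = W2[(size_t)k * nh + j];

  return Rcpp::List::create(
      Rcpp::Named("W1") = W1m, Rcpp::Named("b1") = Rcpp::wrap(b1),
      Rcpp::Named("W2") = W2m, Rcpp::Named("b2") = Rcpp::wrap(b2),
      Rcpp::Named("final_mse") = mse_hist.empty() ? NA_REAL : mse_hist.back(),
      Rcpp::Named("mse_history") = Rcpp::wrap(mse_hist),
      Rcpp::Named("epochs") = epochs,
      Rcpp::Named("converged") = converged);
}
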