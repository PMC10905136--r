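#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

// Deterministic PV-DBOW (distributed bag of words paragraph vectors) with
// negative sampling. Single-threaded, own RNG, fixed update order: two runs
// with the same inputs and seed produce bit-identical vectors on a platform.

namespace {

// splitmix64: small, fast, well-distributed 64-bit generator.
struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next_u64() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform double in [0, 1)
  double next_double() {
    return (next_u64() >> 11) * (1.0 / 9007199254740992.0);
  }
  // uniform integer in [0, n)
  int next_int(int n) {
    return static_cast<int>(next_double() * n);
  }
};

inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// log(sigmoid(x)) computed stably
inline double log_sigmoid(double x) {
  if (x >= 0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}

} // namespace

// Loss of one (doc vector, target word, negative words) triple:
//   L = -[ log sigma(u_w . d) + sum_k log sigma(-u_k . d) ]
// [[Rcpp::export]]
double cpp_pvdbow_point_loss(Rcpp::NumericVector d, Rcpp::NumericVector uw,
                             Rcpp::NumericMatrix uneg) {
  int dim = d.size();
  double s = 0.0;
  for (int j = 0; j < dim; ++j) s += uw[j] * d[j];
  double loss = -log_sigmoid(s);
  for (int k = 0; k < uneg.nrow(); ++k) {
    double sn = 0.0;
    for (int j = 0; j < dim; ++j) sn += uneg(k, j) * d[j];
    loss -= log_sigmoid(-sn);
  }
  return loss;
}

// Analytic gradient of cpp_pvdbow_point_loss with respect to all inputs.
// [[Rcpp::export]]
Rcpp::List cpp_pvdbow_point_grad(Rcpp::NumericVector d, Rcpp::NumericVector uw,
                                 Rcpp::NumericMatrix uneg) {
  int dim = d.size();
  int K = uneg.nrow();
  Rcpp::NumericVector gd(dim), gw(dim);
  Rcpp::NumericMatrix gn(K, dim);

  double s = 0.0;
  for (int j = 0; j < dim; ++j) s += uw[j] * d[j];
  double gpos = sigmoid(s) - 1.0; // d/ds of -log sigma(s)
  for (int j = 0; j < dim; ++j) {
    gw[j] = gpos * d[j];
    gd[j] = gpos * uw[j];
  }
  for (int k = 0; k < K; ++k) {
    double sn = 0.0;
    for (int j = 0; j < dim; ++j) sn += uneg(k, j) * d[j];
    double g = sigmoid(sn); // d/ds of -log sigma(-s)
    for (int j = 0; j < dim; ++j) {
      gn(k, j) = g * d[j];
      gd[j] += g * uneg(k, j);
    }
  }
  return Rcpp::List::create(Rcpp::Named("doc") = gd, Rcpp::Named("word") = gw,
                            Rcpp::Named("neg") = gn);
}

// Train PV-DBOW. docs: list of integer vectors of 0-based vocabulary ids.
// counts: corpus frequency per vocabulary id (negative-sampling distribution
// is counts^0.75). Returns doc vectors, word output vectors and the mean
// objective per epoch.
// [[Rcpp::export]]
Rcpp::List cpp_pvdbow_train(Rcpp::List docs, int vocab_size,
                            Rcpp::NumericVector counts, int dim, int window,
                            int epochs, int negatives, double lr_start,
                            double lr_end, double seed) {
  int n_docs = docs.size();
  std::vector<std::vector<int>> dv(n_docs);
  long long total_positions = 0;
  for (int i = 0; i < n_docs; ++i) {
    Rcpp::IntegerVector x = docs[i];
    dv[i] = std::vector<int>(x.begin(), x.end());
    total_positions += x.size();
  }
  if (total_positions == 0) Rcpp::stop("no trainable positions in corpus");

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> cum(vocab_size);
  double tot = 0.0;
  for (int w = 0; w < vocab_size; ++w) {
    tot += std::pow(counts[w], 0.75);
    cum[w] = tot;
  }

  Rng rng(static_cast<uint64_t>(seed));

  // doc vectors: small uniform init; word output vectors: zero (word2vec
  // convention; symmetric-breaking lives in the doc vectors)
  std::vector<double> D(static_cast<size_t>(n_docs) * dim);
  std::vector<double> W(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < D.size(); ++i)
    D[i] = (rng.next_double() - 0.5) / dim;

  Rcpp::NumericVector epoch_loss(epochs);
  std::vector<double> err(dim);
  long long updates_done = 0;
  double total_updates = static_cast<double>(epochs) * total_positions;

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    for (int di = 0; di < n_docs; ++di) {
      const std::vector<int> &doc = dv[di];
      int L = static_cast<int>(doc.size());
      double *dvec = &D[static_cast<size_t>(di) * dim];
      for (int i = 0; i < L; ++i) {
        double lr = lr_start -
                    (lr_start - lr_end) * (updates_done / total_updates);
        ++updates_done;
        // target sampled from the window span around position i
        int lo = std::max(0, i - window);
        int hi = std::min(L - 1, i + window);
        int target = doc[lo + rng.next_int(hi - lo + 1)];

        std::fill(err.begin(), err.end(), 0.0);
        double *uw = &W[static_cast<size_t>(target) * dim];
        double s = 0.0;
        for (int j = 0; j < dim; ++j) s += uw[j] * dvec[j];
        // share one exp between sigma(s) and -log sigma(s)
        double e = std::exp(-s);
        double sig = 1.0 / (1.0 + e);
        loss_sum += (s >= 0) ? std::log1p(e) : (-s + std::log1p(1.0 / e));
        double g = (sig - 1.0) * lr;
        for (int j = 0; j < dim; ++j) {
          err[j] += g * uw[j];
          uw[j] -= g * dvec[j];
        }
        for (int k = 0; k < negatives; ++k) {
          int neg;
          do {
            double u = rng.next_double() * tot;
            neg = static_cast<int>(
                std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
            if (neg >= vocab_size) neg = vocab_size - 1;
          } while (neg == target);
          double *un = &W[static_cast<size_t>(neg) * dim];
          double sn = 0.0;
          for (int j = 0; j < dim; ++j) sn += un[j] * dvec[j];
          // -log sigma(-sn) with the same exp as sigma(sn)
          double en = std::exp(-sn);
          double sign_ = 1.0 / (1.0 + en);
          loss_sum += (sn >= 0) ? (sn + std::log1p(en)) : std::log1p(1.0 / en);
          double gn = sign_ * lr;
          for (int j = 0; j < dim; ++j) {
            err[j] += gn * un[j];
            un[j] -= gn * dvec[j];
          }
        }
        for (int j = 0; j < dim; ++j) dvec[j] -= err[j];
      }
    }
    double ml = loss_sum / total_positions;
    if (!std::isfinite(ml))
      Rcpp::stop("non-finite training objective at epoch %d", ep + 1);
    epoch_loss[ep] = ml;
    if (ep % 64 == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::NumericMatrix Dm(n_docs, dim), Wm(vocab_size, dim);
  for (int i = 0; i < n_docs; ++i)
    for (int j = 0; j < dim; ++j) Dm(i, j) = D[static_cast<size_t>(i) * dim + j];
  for (int w = 0; w < vocab_size; ++w)
    for (int j = 0; j < dim; ++j) Wm(w, j) = W[static_cast<size_t>(w) * dim + j];

  return Rcpp::List::create(Rcpp::Named("doc_vectors") = Dm,
                            Rcpp::Named("word_vectors") = Wm,
                            Rcpp::Named("epoch_loss") = epoch_loss);
}
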