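// Compute kernel of the dropout multilayer perceptron: forward passes
// (deterministic or with inverted dropout) and Adam training on the
// cross-entropy loss.  All randomness (weight init, shuffling, dropout
// masks) is drawn from R's RNG, so R-level seed handling makes every call
// bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Dropout masks come from a fast internal PCG32 stream seeded from R's RNG
// at entry, so reproducibility under set.seed() is preserved while mask
// generation stays cheap (millions of Bernoulli draws per posterior).
// The generator is integer-only and platform-independent.
struct pcg32 {
  uint64_t state, inc;
  pcg32(uint64_t seed, uint64_t seq) : state(0u), inc((seq << 1u) | 1u) {
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  double unif() { return next() * (1.0 / 4294967296.0); }
};

static pcg32 seeded_pcg() {
  uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t sq = (uint64_t)(unif_rand() * 4294967296.0);
  return pcg32((hi << 32) | lo, sq);
}

static arma::mat dropout_mask(pcg32& rng, arma::uword n, arma::uword m,
                              double keep) {
  arma::mat mask(n, m);
  double inv = 1.0 / keep;
  for (arma::uword i = 0; i < mask.n_elem; ++i) {
    mask(i) = (rng.unif() < keep) ? inv : 0.0;
  }
  return mask;
}

static arma::mat softmax_rows(arma::mat z) {
  z.each_col() -= arma::max(z, 1);
  z = arma::exp(z);
  z.each_col() /= arma::sum(z, 1);
  return z;
}

static void unpack_layers(const List& layers,
                          std::vector<arma::mat>& W,
                          std::vector<arma::rowvec>& b) {
  int L = layers.size();
  W.resize(L);
  b.resize(L);
  for (int l = 0; l < L; ++l) {
    List lay = layers[l];
    W[l] = as<arma::mat>(lay["W"]);
    b[l] = as<arma::rowvec>(lay["b"]);
  }
}

// [[Rcpp::export]]
arma::mat mlp_forward_cpp(List layers, const arma::mat& x,
                          double dropout_rate, bool dropout_active) {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
  unpack_layers(layers, W, b);
  int L = W.size();
  pcg32 rng = seeded_pcg();
  arma::mat a = x;
  for (int l = 0; l < L; ++l) {
    arma::mat z = a * W[l];
    z.each_row() += b[l];
    if (l < L - 1) {
      a = arma::clamp(z, 0.0, arma::datum::inf);
      if (dropout_active && dropout_rate > 0) {
        a %= dropout_mask(rng, a.n_rows, a.n_cols, 1.0 - dropout_rate);
      }
    } else {
      a = softmax_rows(z);
    }
  }
  return a;
}

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& x, const arma::mat& y_onehot,
                   IntegerVector layer_sizes, double dropout_rate,
                   int epochs, int batch_size, double learning_rate) {
  int L = layer_sizes.size() - 1; // layer_sizes = (d, hidden..., C)
  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::rowvec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    int fan_in = layer_sizes[l], fan_out = layer_sizes[l + 1];
    W[l].set_size(fan_in, fan_out);
    double sd = std::sqrt(2.0 / fan_in);
    for (arma::uword i = 0; i < W[l].n_elem; ++i) W[l](i) = norm_rand() * sd;
    b[l].zeros(fan_out);
    mW[l].zeros(fan_in, fan_out);
    vW[l].zeros(fan_in, fan_out);
    mb[l].zeros(fan_out);
    vb[l].zeros(fan_out);
  }

  int n = x.n_rows;
  int bs = std::min(batch_size, n);
  pcg32 rng = seeded_pcg();
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long step = 0;
  arma::uvec ord = arma::regspace<arma::uvec>(0, n - 1);
  std::vector<arma::mat> act(L + 1), mask(L), zs(L);

  for (int epoch = 0; epoch < epochs; ++epoch) {
    // Fisher-Yates shuffle from R's RNG stream
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (int start = 0; start < n; start += bs) {
      int stop = std::min(start + bs, n) - 1;
      arma::uvec take = ord.subvec(start, stop);
      act[0] = x.rows(take);
      // forward with cached pre-activations and masks
      for (int l = 0; l < L; ++l) {
        arma::mat z = act[l] * W[l];
        z.each_row() += b[l];
        if (l < L - 1) {
          zs[l] = z;
          arma::mat h = arma::clamp(z, 0.0, arma::datum::inf);
          if (dropout_rate > 0) {
            mask[l] = dropout_mask(rng, h.n_rows, h.n_cols,
                                   1.0 - dropout_rate);
            h %= mask[l];
          }
          act[l + 1] = h;
        } else {
          act[l + 1] = softmax_rows(z);
        }
      }
      // backward
      arma::mat delta = (act[L] - y_onehot.rows(take)) / (double)take.n_elem;
      ++step;
      double corr1 = 1.0 - std::pow(beta1, (double)step);
      double corr2 = 1.0 - std::pow(beta2, (double)step);
      for (int l = L - 1; l >= 0; --l) {
        arma::mat gW = act[l].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          if (dropout_rate > 0) delta %= mask[l - 1];
          delta %= arma::conv_to<arma::mat>::from(zs[l - 1] > 0);
        }
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * (gW % gW);
        W[l] -= learning_rate * (mW[l] / corr1) /
                (arma::sqrt(vW[l] / corr2) + eps);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * (gb % gb);
        b[l] -= learning_rate * (mb[l] / corr1) /
                (arma::sqrt(vb[l] / corr2) + eps);
      }
    }
  }

  List out(L);
  for (int l = 0; l < L; ++l) {
    out[l] = List::create(Named("W") = W[l], Named("b") = b[l]);
  }
  return out;
}
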