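// MCMC core for the latent-edge graphical model.
//
// Per batch: gamma ~ TruncNormal(mu, sigma, lo, hi) shared across genes;
// per gene six bounded mixture latents; one Bernoulli(gamma) indicator per
// candidate (real or control). Indicators are updated by exact Gibbs (the
// only coupling is the gene's any-edge disjunction over real candidates);
// continuous latents by shrinkage slice sampling on their bounded support,
// which is rejection-free in the limit and needs no tuning.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// log density of the Beta(a,1)/Beta(a0,1) null mixture at log-value lx
static inline double null_ll(double lx, double r, double a1, double a0) {
  if (r <= 0.0) return std::log(a0) + (a0 - 1.0) * lx;
  if (r >= 1.0) return std::log(a1) + (a1 - 1.0) * lx;
  return lse2(std::log(r) + std::log(a1) + (a1 - 1.0) * lx,
              std::log(1.0 - r) + std::log(a0) + (a0 - 1.0) * lx);
}

static inline double edge_ll(double lx, double a1) {
  return std::log(a1) + (a1 - 1.0) * lx;
}

struct Rng {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  explicit Rng(uint64_t seed) : eng(seed) {}
  double runif() { return unif(eng); }
  double runif(double lo, double hi) { return lo + (hi - lo) * unif(eng); }
};

// Shrinkage slice sampler on a bounded interval.
template <typename F>
static double slice_bounded(double x0, double lo, double hi, F logpost, Rng& rng) {
  double y = logpost(x0) + std::log(rng.runif());
  double L = lo, R = hi;
  for (int it = 0; it < 200; ++it) {
    double x1 = rng.runif(L, R);
    if (logpost(x1) >= y) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0;
}

// [[Rcpp::export]]
List sample_batch_cpp(NumericVector p_pheno, IntegerVector gene_index,
                      NumericVector p_gex, NumericVector p_chip,
                      LogicalVector is_control,
                      double mu_gamma, double sigma_gamma,
                      double lo, double hi, double alpha_prime,
                      bool use_p, bool use_q, bool prior_only,
                      int n_tune, int n_draws, int n_chains, int n_burn,
                      int seed) {
  const int G = p_pheno.size();
  const int K = gene_index.size();

  std::vector<double> lP(G), lp(K), lq(K);
  for (int j = 0; j < G; ++j) lP[j] = std::log(p_pheno[j]);
  for (int k = 0; k < K; ++k) {
    lp[k] = std::log(p_gex[k]);
    lq[k] = std::log(p_chip[k]);
  }
  const double la = std::log(alpha_prime);

  // candidate lists per gene
  std::vector<std::vector<int>> cand(G);
  for (int k = 0; k < K; ++k) cand[gene_index[k]].push_back(k);
  for (int j = 0; j < G; ++j)
    if (cand[j].empty()) stop("gene %d has no candidates", j + 1);

  const int n_keep = n_draws - n_burn;
  std::vector<double> pooled_sum(K, 0.0);
  // per (indicator, chain, half) sums of binary draws for split-R-hat
  std::vector<double> half_sum(static_cast<size_t>(K) * n_chains * 2, 0.0);
  const int half_len = n_keep / 2;  // second half gets the remainder

  for (int c = 0; c < n_chains; ++c) {
    Rng rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL +
            1442695040888963407ULL * (c + 1));
    double gamma = mu_gamma;
    std::vector<double> rG(G, 0.5), aG1(G, 0.25), aG0(G, 0.75);
    std::vector<double> rC(G, 0.5), aC1(G, 0.25), aC0(G, 0.75);
    std::vector<int> T(K);
    std::vector<int> n_active(G, 0);  // active REAL edges per gene
    int nT1 = 0;
    for (int k = 0; k < K; ++k) {
      T[k] = rng.runif() < gamma ? 1 : 0;
      nT1 += T[k];
      if (T[k] && !is_control[k]) n_active[gene_index[k]] += 1;
    }

    for (int iter = 0; iter < n_tune + n_draws; ++iter) {
      // -- gamma | T  (slice on (lo, hi))
      {
        int n1 = nT1, n0 = K - nT1;
        auto lpost = [&](double g) {
          if (g <= 0.0 || g >= 1.0) return R_NegInf;
          double v = -0.5 * (g - mu_gamma) * (g - mu_gamma) /
                     (sigma_gamma * sigma_gamma);
          if (n1 > 0) v += n1 * std::log(g);
          if (n0 > 0) v += n0 * std::log(1.0 - g);
          return v;
        };
        gamma = slice_bounded(gamma, lo, hi, lpost, rng);
      }

      if (!prior_only) {
        // -- per-gene mixture latents | T
        for (int j = 0; j < G; ++j) {
          const std::vector<int>& ck = cand[j];
          if (use_p) {
            auto lr = [&](double r) {
              double v = 0.0;
              for (int k : ck) if (!T[k]) v += null_ll(lp[k], r, aG1[j], aG0[j]);
              return v;
            };
            rG[j] = slice_bounded(rG[j], 1e-9, 1.0 - 1e-9, lr, rng);
            auto la1 = [&](double a1) {
              double v = 0.0;
              for (int k : ck)
                v += T[k] ? edge_ll(lp[k], a1) : null_ll(lp[k], rG[j], a1, aG0[j]);
              return v;
            };
            aG1[j] = slice_bounded(aG1[j], 1e-9, 0.5, la1, rng);
            auto la0 = [&](double a0) {
              double v = 0.0;
              for (int k : ck) if (!T[k]) v += null_ll(lp[k], rG[j], aG1[j], a0);
              return v;
            };
            aG0[j] = slice_bounded(aG0[j], 0.5, 1.0, la0, rng);
          }
          if (use_q) {
            auto lr = [&](double r) {
              double v = 0.0;
              for (int k : ck) if (!T[k]) v += null_ll(lq[k], r, aC1[j], aC0[j]);
              return v;
            };
            rC[j] = slice_bounded(rC[j], 1e-9, 1.0 - 1e-9, lr, rng);
            auto la1 = [&](double a1) {
              double v = 0.0;
              for (int k : ck)
                v += T[k] ? edge_ll(lq[k], a1) : null_ll(lq[k], rC[j], a1, aC0[j]);
              return v;
            };
            aC1[j] = slice_bounded(aC1[j], 1e-9, 0.5, la1, rng);
            auto la0 = [&](double a0) {
              double v = 0.0;
              for (int k : ck) if (!T[k]) v += null_ll(lq[k], rC[j], aC1[j], a0);
              return v;
            };
            aC0[j] = slice_bounded(aC0[j], 0.5, 1.0, la0, rng);
          }
        }
      }

      // -- indicators | rest  (exact Gibbs)
      const double lg = std::log(gamma), l1g = std::log(1.0 - gamma);
      for (int k = 0; k < K; ++k) {
        const int j = gene_index[k];
        double lp1 = lg, lp0 = l1g;
        if (!prior_only) {
          if (use_p) {
            lp1 += edge_ll(lp[k], aG1[j]);
            lp0 += null_ll(lp[k], rG[j], aG1[j], aG0[j]);
          }
          if (use_q) {
            lp1 += edge_ll(lq[k], aC1[j]);
            lp0 += null_ll(lq[k], rC[j], aC1[j], aC0[j]);
          }
          const double pheno1 = la + (alpha_prime - 1.0) * lP[j];
          if (is_control[k]) {
            lp1 += pheno1;  // replica observes P_j under its own indicator
          } else {
            const int others = n_active[j] - T[k];
            lp1 += pheno1;
            if (others > 0) lp0 += pheno1;  // disjunction already active
          }
        }
        const int t_new = rng.runif() < 1.0 / (1.0 + std::exp(lp0 - lp1)) ? 1 : 0;
        if (t_new != T[k]) {
          nT1 += t_new - T[k];
          if (!is_control[k]) n_active[j] += t_new - T[k];
          T[k] = t_new;
        }
      }

      // -- record
      const int d = iter - n_tune;
      if (d >= n_burn) {
        const int r = d - n_burn;
        const int half = r < half_len ? 0 : 1;
        double* hs = &half_sum[(static_cast<size_t>(c) * 2 + half) * K];
        for (int k = 0; k < K; ++k) {
          pooled_sum[k] += T[k];
          hs[k] += T[k];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericVector score(K), rhat(K);
  const double n_total = static_cast<double>(n_keep) * n_chains;
  const int M = 2 * n_chains;
  const double len0 = half_len, len1 = n_keep - half_len;
  for (int k = 0; k < K; ++k) {
    score[k] = pooled_sum[k] / n_total;
    // split-R-hat over M = 2*n_chains binary half-sequences
    double gm = 0.0, W = 0.0, B = 0.0;
    std::vector<double> means(M);
    for (int c = 0; c < n_chains; ++c)
      for (int h = 0; h < 2; ++h) {
        double len = h == 0 ? len0 : len1;
        double m = half_sum[(static_cast<size_t>(c) * 2 + h) * K + k] / len;
        means[c * 2 + h] = m;
        gm += m / M;
        W += (len / (len - 1.0)) * m * (1.0 - m) / M;  // binary: sumsq == sum
      }
    for (int m = 0; m < M; ++m) B += (means[m] - gm) * (means[m] - gm);
    B *= len0 / (M - 1.0);
    if (W > 0.0) {
      double varp = (len0 - 1.0) / len0 * W + B / len0;
      rhat[k] = std::sqrt(varp / W);
    } else {
      rhat[k] = NA_REAL;  // all chains constant
    }
  }
  return List::create(_["score"] = score, _["rhat"] = rhat);
}
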