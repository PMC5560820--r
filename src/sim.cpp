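// Euler-Maruyama integrators for networks of SNIC-proximal nodes:
// the 10-ODE Wendling neural mass and the theta-neuron canonical model.
//
// Noise is white with intensity sigma (<xi(t) xi(t')> = sigma^2 delta(t-t')),
// so the discrete increment has standard deviation sigma * sqrt(dt).
//
// Each node carries its own counter-based RNG stream keyed by (seed, node id)
// so that noise stays attached to surviving nodes across virtual resections
// (common-random-number evaluation of BNI differences).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---- RNG: splitmix64-seeded xoshiro256+, Box-Muller normals ----

struct Xoshiro256 {
  uint64_t s[4];
  double spare;
  bool has_spare;

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t seed_val) {
    uint64_t x = seed_val;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    has_spare = false;
    spare = 0.0;
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1)
  double runif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // Marsaglia polar method: two normals per accepted pair, no trig
  double rnorm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

static void seed_streams(std::vector<Xoshiro256> &rng, uint64_t seed,
                         const IntegerVector &node_ids) {
  int n = node_ids.size();
  rng.resize(n);
  for (int j = 0; j < n; ++j) {
    uint64_t key = seed;
    // mix the node label in so streams are a function of (seed, label), not
    // of the node's position in the current (possibly resected) network
    uint64_t x = key ^ (0x632BE59BD9B4E019ULL * (uint64_t)(node_ids[j] + 1));
    rng[j].seed(Xoshiro256::splitmix64(x));
  }
}

// ---- canonical model (theta neuron) ----

// theta_dot_j = (1 - cos theta_j) + (1 + cos theta_j) * I_j(t)
// I_j(t) = I0_j + xi_j(t) + (1/N) sum_{i != j} w a_ij (1 - cos(theta_i - theta_s_i))
//
// Returns output Y_j = 1 - cos(theta_j - theta_s_j) subsampled every `stride`
// steps, plus the per-node count of full rotations through theta_s + pi
// (upward crossings, unwrapped phase).
// [[Rcpp::export]]
List simulate_cm_cpp(int n, IntegerVector edge_src, IntegerVector edge_dst,
                     NumericVector edge_w, NumericVector I0,
                     NumericVector theta_s, double sigma, double inv_pref,
                     double duration, double dt, int stride,
                     double transient, double seed_val,
                     IntegerVector node_ids) {
  int n_steps = (int)std::round(duration / dt);
  int n_trans = (int)std::round(transient / dt);
  int n_out = n_steps / stride;
  int n_edges = edge_src.size();

  std::vector<Xoshiro256> rng;
  seed_streams(rng, (uint64_t)seed_val, node_ids);

  std::vector<double> theta(n), phase(n), cth(n), sth(n), out_now(n), acc(n);
  std::vector<double> cs(n), ss(n);
  std::vector<int> spikes(n, 0);
  for (int j = 0; j < n; ++j) {
    theta[j] = theta_s[j];
    phase[j] = 0.0;  // unwrapped displacement from theta_s
    cs[j] = std::cos(theta_s[j]);
    ss[j] = std::sin(theta_s[j]);
  }

  NumericMatrix Y(n, n_out);
  double sq = sigma * std::sqrt(dt);
  int i_out = 0;

  for (int step = -n_trans; step < n_steps; ++step) {
    for (int j = 0; j < n; ++j) {
#if defined(__GNUC__) && defined(_GNU_SOURCE)
      sincos(theta[j], &sth[j], &cth[j]);
#else
      cth[j] = std::cos(theta[j]);
      sth[j] = std::sin(theta[j]);
#endif
      // 1 - cos(theta_j - theta_s_j)
      out_now[j] = 1.0 - (cth[j] * cs[j] + sth[j] * ss[j]);
      acc[j] = 0.0;
    }
    for (int e = 0; e < n_edges; ++e)
      acc[edge_dst[e]] += edge_w[e] * out_now[edge_src[e]];
    for (int j = 0; j < n; ++j) {
      double Ij = I0[j] + inv_pref * acc[j];
      double one_p = 1.0 + cth[j];
      double dtheta = dt * ((1.0 - cth[j]) + one_p * Ij) +
                      one_p * sq * rng[j].rnorm();
      theta[j] += dtheta;
      if (step >= 0) {
        double old_phase = phase[j];
        phase[j] += dtheta;
        // upward crossing of theta_s + pi (phase displacement pi mod 2pi)
        double p0 = std::floor((old_phase - M_PI) / (2.0 * M_PI));
        double p1 = std::floor((phase[j] - M_PI) / (2.0 * M_PI));
        if (p1 > p0) spikes[j] += (int)(p1 - p0);
      }
    }
    if (step >= 0 && ((step + 1) % stride == 0) && i_out < n_out) {
      for (int j = 0; j < n; ++j)
        Y(j, i_out) = 1.0 - std::cos(theta[j] - theta_s[j]);
      ++i_out;
    }
  }

  return List::create(_["output"] = Y,
                      _["spike_count"] = IntegerVector(spikes.begin(), spikes.end()),
                      _["dt_out"] = dt * stride);
}

// ---- Wendling neural mass ----

static inline double sigm(double v, double two_e0, double r, double v0) {
  return two_e0 / (1.0 + std::exp(r * (v0 - v)));
}

// 10 first-order ODEs per node; node input
//   p_j(t) = p0_j + xi_j(t) + (1/N) sum_i lambda a_ij S(z2_i - z3_i - z4_i)
// Noise enters the z7 equation through p (increment A*a*sigma*sqrt(dt)).
// Output is z2 - z3 - z4, subsampled every `stride` steps.
// [[Rcpp::export]]
List simulate_wm_cpp(int n, IntegerVector edge_src, IntegerVector edge_dst,
                     NumericVector edge_w, NumericVector p0,
                     double sigma, double inv_pref,
                     NumericVector par,  // A,a,B,b,G,g,C1..C7,v0,e0,r
                     double duration, double dt, int stride,
                     double transient, double seed_val,
                     IntegerVector node_ids) {
  double A = par[0], a = par[1], B = par[2], b = par[3], G = par[4], g = par[5];
  double C1 = par[6], C2 = par[7], C3 = par[8], C4 = par[9], C5 = par[10],
         C6 = par[11], C7 = par[12];
  double v0 = par[13], e0 = par[14], r = par[15];
  double two_e0 = 2.0 * e0;

  int n_steps = (int)std::round(duration / dt);
  int n_trans = (int)std::round(transient / dt);
  int n_out = n_steps / stride;
  int n_edges = edge_src.size();

  std::vector<Xoshiro256> rng;
  seed_streams(rng, (uint64_t)seed_val, node_ids);

  // state: z[j][0..9]
  std::vector<double> z(10 * n, 0.0), dz(10 * n), out_now(n), acc(n);
  NumericMatrix Y(n, n_out);
  double sq = A * a * sigma * std::sqrt(dt);
  int i_out = 0;

  for (int step = -n_trans; step < n_steps; ++step) {
    for (int j = 0; j < n; ++j)
      out_now[j] = sigm(z[10 * j + 1] - z[10 * j + 2] - z[10 * j + 3],
                        two_e0, r, v0);
    for (int j = 0; j < n; ++j) acc[j] = 0.0;
    for (int e = 0; e < n_edges; ++e)
      acc[edge_dst[e]] += edge_w[e] * out_now[edge_src[e]];

    for (int j = 0; j < n; ++j) {
      double *zj = &z[10 * j];
      double *dzj = &dz[10 * j];
      double pj = p0[j] + inv_pref * acc[j];
      double S_py = out_now[j];                       // S(z2 - z3 - z4)
      double S_c1 = sigm(C1 * zj[0], two_e0, r, v0);  // S(C1 z1)
      double S_c3 = sigm(C3 * zj[0], two_e0, r, v0);  // S(C3 z1)
      double S_c5 = sigm(C5 * zj[0] - zj[4], two_e0, r, v0);
      dzj[0] = zj[5];
      dzj[1] = zj[6];
      dzj[2] = zj[7];
      dzj[3] = zj[8];
      dzj[4] = zj[9];
      dzj[5] = A * a * S_py - 2.0 * a * zj[5] - a * a * zj[0];
      dzj[6] = A * a * (pj + C2 * S_c1) - 2.0 * a * zj[6] - a * a * zj[1];
      dzj[7] = B * b * C4 * S_c3 - 2.0 * b * zj[7] - b * b * zj[2];
      dzj[8] = G * g * C7 * S_c5 - 2.0 * g * zj[8] - g * g * zj[3];
      dzj[9] = B * b * C6 * S_c3 - 2.0 * b * zj[9] - b * b * zj[4];
      for (int k = 0; k < 10; ++k) zj[k] += dt * dzj[k];
      zj[6] += sq * rng[j].rnorm();
      if (!std::isfinite(zj[6]))
        stop("non-finite state during Wendling integration (dt too large?)");
    }
    if (step >= 0 && ((step + 1) % stride == 0) && i_out < n_out) {
      for (int j = 0; j < n; ++j)
        Y(j, i_out) = z[10 * j + 1] - z[10 * j + 2] - z[10 * j + 3];
      ++i_out;
    }
  }

  return List::create(_["output"] = Y, _["dt_out"] = dt * stride);
}
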