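// Delay-coupled network of SJ3D (reduced Hindmarsh-Rose) neural masses,
// integrated with the stochastic Heun scheme (additive noise, predictor and
// corrector sharing one Gaussian increment; increment = sd * sqrt(dt) * Z).
//
// Time unit is ms throughout.  The history buffer stores the per-region
// quadrature-weighted excitatory mean field x_i(t); the afferent input to
// region i is c * sum_j w_ij * x_j(t - dt_ij), evaluated once per step from
// the buffer (delays are >= 1 step, so both Heun stages see known history).
// Recording block-averages the mean field over each recording stride, which
// doubles as an anti-alias filter ahead of the hemodynamic stage.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <cstdlib>
#include <random>
#include <vector>
#ifdef __SSE2__
#include <xmmintrin.h>
#endif

using namespace Rcpp;

namespace {

// Self-contained mt19937_64 engine + Marsaglia-Tsang ziggurat normal
// sampler: deterministic for a given seed independent of the C++ standard
// library's std::normal_distribution implementation, and fast enough for
// the ~10^9 draws a full-length whole-brain run needs.
struct NormRng {
  std::mt19937_64 eng;
  uint32_t half;
  bool has_half;
  uint32_t kn[128];
  double wn[128], fn[128];

  explicit NormRng(uint64_t seed) : eng(seed), half(0), has_half(false) {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<uint32_t>((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  uint32_t next_u32() {
    if (has_half) { has_half = false; return half; }
    uint64_t v = eng();
    half = static_cast<uint32_t>(v >> 32);
    has_half = true;
    return static_cast<uint32_t>(v);
  }
  double unif() {  // 53-bit uniform in (0, 1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    for (;;) {
      int32_t hz = static_cast<int32_t>(next_u32());
      uint32_t iz = static_cast<uint32_t>(hz) & 127u;
      if (static_cast<uint32_t>(hz < 0 ? -static_cast<int64_t>(hz) : hz) < kn[iz])
        return hz * wn[iz];
      if (iz == 0) {  // tail beyond +/- r
        const double r = 3.442619855899;
        double x, y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -r - x;
      }
      double x = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
    }
  }
};

struct Edge { int i; int j; double w; int d; };

// Flush denormals to zero inside the integrator: trajectories relaxing to a
// fixed point otherwise hit gradual-underflow penalties that slow the loop
// by an order of magnitude.  State restored on scope exit.
struct FtzGuard {
#ifdef __SSE2__
  unsigned int saved;
  FtzGuard() : saved(_mm_getcsr()) { _mm_setcsr(saved | 0x8040); }
  ~FtzGuard() { _mm_setcsr(saved); }
#else
  FtzGuard() {}
#endif
};

} // namespace

// [[Rcpp::export(name = ".sj3d_network_heun")]]
List sj3d_network_heun(NumericMatrix weights, IntegerMatrix delays,
                       List par, NumericVector IE, NumericVector II,
                       NumericVector mode_w,
                       double coupling_c, double dt,
                       int n_steps, int burn_steps, int record_every,
                       NumericVector noise_sd6, double seed,
                       NumericMatrix init_state) {
  FtzGuard ftz;
  const int N = weights.nrow();
  const int M = IE.size();
  const double a = par["a"], b = par["b"], cc = par["c"], d = par["d"],
               r = par["r"], s = par["s"], x0 = par["x0"],
               b_inh = par["b_inh"], d_inh = par["d_inh"],
               K11 = par["K11"], K12 = par["K12"], K21 = par["K21"];

  // state: 6 families x N x M, flattened [family][i*M + k]
  const int NM = N * M;
  std::vector<double> st(6 * NM), pred(6 * NM), f1(6 * NM), f2(6 * NM),
      noise(6 * NM);
  for (int f = 0; f < 6; ++f)
    for (int e = 0; e < NM; ++e)
      st[f * NM + e] = init_state(f, e);

  // edge list over nonzero weights; within each target region the incoming
  // edges are ordered by (weight, delay) so the afferent sum is evaluated in
  // a relabeling-invariant order (region permutations then permute
  // trajectories exactly, not just up to rounding)
  std::vector<Edge> edges;
  int max_delay = 1;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (weights(i, j) != 0.0 && i != j) {
        Edge e; e.i = i; e.j = j; e.w = weights(i, j); e.d = delays(i, j);
        if (e.d < 1) e.d = 1;
        if (e.d > max_delay) max_delay = e.d;
        edges.push_back(e);
      }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& a, const Edge& b) {
                     if (a.i != b.i) return a.i < b.i;
                     if (a.w != b.w) return a.w < b.w;
                     return a.d < b.d;
                   });

  const int H = max_delay + 1;
  std::vector<double> hist(static_cast<size_t>(H) * N);
  std::vector<double> xbar(N), abar(N), aff(N);

  auto mean_fields = [&](const std::vector<double>& S) {
    for (int i = 0; i < N; ++i) {
      double sx = 0.0, sa = 0.0;
      for (int k = 0; k < M; ++k) {
        sx += mode_w[k] * S[0 * NM + i * M + k];
        sa += mode_w[k] * S[3 * NM + i * M + k];
      }
      xbar[i] = sx; abar[i] = sa;
    }
  };

  auto drift = [&](const std::vector<double>& S, std::vector<double>& D) {
    // xbar/abar and aff must be current for S (aff depends on history only)
    for (int i = 0; i < N; ++i) {
      const double xb = xbar[i], ab = abar[i], A = aff[i];
      for (int k = 0; k < M; ++k) {
        const int e = i * M + k;
        const double xi = S[0 * NM + e], eta = S[1 * NM + e],
                     tau = S[2 * NM + e], al = S[3 * NM + e],
                     be = S[4 * NM + e], ga = S[5 * NM + e];
        D[0 * NM + e] = eta - a * xi * xi * xi + b * xi * xi - tau +
                        K11 * (xb - xi) - K21 * (ab - xi) + IE[k] + A;
        D[1 * NM + e] = cc - d * xi * xi - eta;
        D[2 * NM + e] = r * s * (xi - x0) - r * tau;
        D[3 * NM + e] = be - a * al * al * al + b_inh * al * al - ga +
                        K12 * (xb - al) + II[k];
        D[4 * NM + e] = cc - d_inh * al * al - be;
        D[5 * NM + e] = r * s * (al - x0) - r * ga;
      }
    }
  };

  // prime history with the initial mean field
  mean_fields(st);
  for (int h = 0; h < H; ++h)
    for (int i = 0; i < N; ++i) hist[static_cast<size_t>(h) * N + i] = xbar[i];

  NormRng rng(static_cast<uint64_t>(seed));
  const double sqdt = std::sqrt(dt);
  double nsd[6];
  for (int f = 0; f < 6; ++f) nsd[f] = noise_sd6[f] * sqdt;
  const bool any_noise = nsd[0] + nsd[1] + nsd[2] + nsd[3] + nsd[4] + nsd[5] > 0.0;

  const int rec_steps = n_steps - burn_steps;
  const int n_rec = rec_steps / record_every;
  NumericMatrix out(N, n_rec);
  std::vector<double> acc(N, 0.0);
  int acc_n = 0, rec_idx = 0;

  for (int t = 0; t < n_steps; ++t) {
    const int slot = t % H;
    // afferent from history (x_j at time t - d*dt; slot t holds x(t))
    mean_fields(st);
    for (int i = 0; i < N; ++i) hist[static_cast<size_t>(slot) * N + i] = xbar[i];
    std::fill(aff.begin(), aff.end(), 0.0);
    if (coupling_c != 0.0)
      for (const Edge& e : edges) {
        int hs = slot - e.d; if (hs < 0) hs += H;
        aff[e.i] += e.w * hist[static_cast<size_t>(hs) * N + e.j];
      }
    if (coupling_c != 0.0 && coupling_c != 1.0)
      for (int i = 0; i < N; ++i) aff[i] *= coupling_c;

    drift(st, f1);
    if (any_noise) {
      for (int f = 0; f < 6; ++f) {
        const double sf = nsd[f];
        if (sf > 0.0)
          for (int e = 0; e < NM; ++e) noise[f * NM + e] = sf * rng.norm();
        else
          for (int e = 0; e < NM; ++e) noise[f * NM + e] = 0.0;
      }
    }
    for (int q = 0; q < 6 * NM; ++q)
      pred[q] = st[q] + dt * f1[q] + (any_noise ? noise[q] : 0.0);
    mean_fields(pred);  // aff unchanged (history-only)
    drift(pred, f2);
    for (int q = 0; q < 6 * NM; ++q)
      st[q] += 0.5 * dt * (f1[q] + f2[q]) + (any_noise ? noise[q] : 0.0);

    if ((t & 1023) == 0) {
      for (int i = 0; i < N; ++i)
        if (!std::isfinite(st[i * M])) {
          stop("divergence at step %d, region %d (coupling=%g): non-finite state",
               t, i + 1, coupling_c);
        }
    }

    if (t >= burn_steps && rec_idx < n_rec) {
      mean_fields(st);
      for (int i = 0; i < N; ++i) acc[i] += xbar[i];
      if (++acc_n == record_every) {
        for (int i = 0; i < N; ++i) {
          double v = acc[i] / record_every;
          if (!std::isfinite(v))
            stop("divergence at step %d, region %d (coupling=%g)", t, i + 1,
                 coupling_c);
          out(i, rec_idx) = v;
          acc[i] = 0.0;
        }
        acc_n = 0;
        ++rec_idx;
      }
    }
  }

  NumericVector times(n_rec);
  for (int k = 0; k < n_rec; ++k)
    times[k] = (burn_steps + (k + 1.0) * record_every) * dt / 1000.0;  // s

  NumericMatrix final_state(6, NM);
  for (int f = 0; f < 6; ++f)
    for (int e = 0; e < NM; ++e) final_state(f, e) = st[f * NM + e];

  return List::create(_["times"] = times, _["values"] = out,
                      _["final_state"] = final_state);
}
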