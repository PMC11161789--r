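// Euler-Maruyama integration of the FIC neural-mass model on a connectome,
// feedback-inhibition calibration, and the Balloon-Windkessel BOLD forward
// model. Stochastic integration uses a self-contained xoshiro256++ RNG
// (seeded from the caller-supplied integer) with polar-method normal
// draws, so trajectories are bit-reproducible across platforms and
// independent of R's RNG state.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool has_spare = false;
  double spare = 0.0;
  inline double normal() { // Marsaglia polar method
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

} // namespace

// Sigmoidal frequency-current curve H(x) = (a*x - b) / (1 - exp(-d*(a*x - b))).
// The singularity at a*x = b is removable; H -> 1/d there.
static inline double transfer_scalar(double x, double a, double b, double d) {
  double y = a * x - b;
  double e = d * y;
  if (std::fabs(e) < 1e-8) return (1.0 + 0.5 * e) / d; // 2nd-order expansion
  return y / (1.0 - std::exp(-e));
}

// [[Rcpp::export]]
arma::vec cpp_rng_normals(int seed, int n) {
  Xoshiro rng((uint64_t)seed);
  arma::vec out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.normal();
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_transfer(const arma::vec& x, double a, double b, double d) {
  arma::vec out(x.n_elem);
  for (arma::uword i = 0; i < x.n_elem; ++i)
    out[i] = transfer_scalar(x[i], a, b, d);
  return out;
}

struct NeuralConsts {
  double aE, bE, dE, aI, bI, dI, tauE, tauI, gamma, J, I0, WE, WI;
};

static NeuralConsts unpack_nc(const List& nc) {
  NeuralConsts c;
  c.aE = nc["a_e"]; c.bE = nc["b_e"]; c.dE = nc["d_e"];
  c.aI = nc["a_i"]; c.bI = nc["b_i"]; c.dI = nc["d_i"];
  c.tauE = nc["tau_e"]; c.tauI = nc["tau_i"]; c.gamma = nc["gamma"];
  c.J = nc["j_coupling"]; c.I0 = nc["i0"]; c.WE = nc["w_e"]; c.WI = nc["w_i"];
  return c;
}

// One deterministic drift evaluation; fills rates and derivatives.
// Allocation-free: the coupling matvec and all outputs are written into
// caller-owned buffers (the per-step cost at n ~ 68 is dominated by
// allocation and library-call overhead otherwise).
static inline void drift(const arma::mat& sc, const arma::vec& wEE,
                         const arma::vec& wEI, const arma::vec& wIE,
                         double G, const NeuralConsts& c,
                         const arma::vec& sE, const arma::vec& sI,
                         arma::vec& rE, arma::vec& rI,
                         arma::vec& dsE, arma::vec& dsI) {
  const arma::uword n = sE.n_elem;
  const double GJ = G * c.J;
  const double* se = sE.memptr();
  const double* si = sI.memptr();
  // coup_i = GJ * sum_j sc_ij * se_j ; sc is symmetric, walk columns
  for (arma::uword i = 0; i < n; ++i) dsE[i] = 0.0; // reuse dsE as coup acc
  for (arma::uword j = 0; j < n; ++j) {
    const double* col = sc.colptr(j);
    const double sj = se[j];
    if (sj == 0.0) continue;
    for (arma::uword i = 0; i < n; ++i) dsE[i] += col[i] * sj;
  }
  for (arma::uword i = 0; i < n; ++i) {
    const double iE = c.WE * c.I0 + c.J * wEE[i] * se[i] + GJ * dsE[i] -
                      wIE[i] * si[i];
    const double iI = c.WI * c.I0 + c.J * wEI[i] * se[i] - si[i]; // w_II = 1
    rE[i] = transfer_scalar(iE, c.aE, c.bE, c.dE);
    rI[i] = transfer_scalar(iI, c.aI, c.bI, c.dI);
    dsE[i] = -se[i] / c.tauE + c.gamma * (1.0 - se[i]) * rE[i];
    dsI[i] = -si[i] / c.tauI + rI[i];
  }
}

// [[Rcpp::export]]
List cpp_drift(const arma::mat& sc, const arma::vec& wEE, const arma::vec& wEI,
               const arma::vec& wIE, double G, const List& nc,
               const arma::vec& sE, const arma::vec& sI) {
  NeuralConsts c = unpack_nc(nc);
  arma::uword n = sE.n_elem;
  arma::vec rE(n), rI(n), dsE(n), dsI(n);
  drift(sc, wEE, wEI, wIE, G, c, sE, sI, rE, rI, dsE, dsI);
  return List::create(_["ds_e"] = dsE, _["ds_i"] = dsI,
                      _["r_e"] = rE, _["r_i"] = rI);
}

// Balloon-Windkessel state (per region): z (vasodilatory signal), f (inflow),
// v (blood volume), q (deoxyhemoglobin). Euler step at the neural dt.
struct BWConsts {
  double kappa, gammah, tauh, alpha, rho, V0, k1, k2, k3;
};

static BWConsts unpack_hc(const List& hc) {
  BWConsts h;
  h.kappa = hc["kappa"]; h.gammah = hc["gamma_h"]; h.tauh = hc["tau_h"];
  h.alpha = hc["alpha"]; h.rho = hc["rho"]; h.V0 = hc["v0"];
  h.k1 = hc["k1"]; h.k2 = hc["k2"]; h.k3 = hc["k3"];
  return h;
}

static inline void bw_step(const BWConsts& h, double dt, const arma::vec& u,
                           arma::vec& z, arma::vec& f, arma::vec& v,
                           arma::vec& q) {
  arma::uword n = u.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    double fi = std::max(f[i], 1e-6);
    double vi = std::max(v[i], 1e-6);
    double dz = u[i] - h.kappa * z[i] - h.gammah * (fi - 1.0);
    double df = z[i];
    double dv = (fi - std::pow(vi, 1.0 / h.alpha)) / h.tauh;
    double E = 1.0 - std::pow(1.0 - h.rho, 1.0 / fi);
    double dq = (fi * E / h.rho - q[i] * std::pow(vi, 1.0 / h.alpha - 1.0)) /
                h.tauh;
    z[i] += dz * dt; f[i] += df * dt; v[i] += dv * dt; q[i] += dq * dt;
  }
}

static inline arma::vec bw_readout(const BWConsts& h, const arma::vec& v,
                                   const arma::vec& q) {
  return h.V0 * (h.k1 * (1.0 - q) + h.k2 * (1.0 - q / v) + h.k3 * (1.0 - v));
}

// Standalone Balloon-Windkessel forward model driven by a supplied synaptic
// activity matrix (steps x regions), sampled every tr_steps neural steps.
// [[Rcpp::export]]
List cpp_balloon_windkessel(const arma::mat& s_e, double dt, int tr_steps,
                            const List& hc) {
  BWConsts h = unpack_hc(hc);
  arma::uword n = s_e.n_cols, T = s_e.n_rows;
  arma::vec z(n, arma::fill::zeros), f(n, arma::fill::ones),
      v(n, arma::fill::ones), q(n, arma::fill::ones);
  arma::uword n_samp = T / (arma::uword)tr_steps;
  arma::mat bold(n_samp, n);
  arma::uword k = 0;
  for (arma::uword t = 0; t < T; ++t) {
    arma::vec u = s_e.row(t).t();
    bw_step(h, dt, u, z, f, v, q);
    if (!z.is_finite() || !v.is_finite() || !q.is_finite())
      stop("non-finite hemodynamic state at step %d", (int)t + 1);
    if ((t + 1) % (arma::uword)tr_steps == 0 && k < n_samp)
      bold.row(k++) = bw_readout(h, v, q).t();
  }
  return List::create(_["bold"] = bold, _["f"] = f, _["v"] = v, _["q"] = q);
}

// Stochastic (or noise-free) integration of the coupled gating equations,
// with optional in-loop hemodynamics. Retains subsampled trajectories
// (every record_stride-th post-burn-in step) plus full-resolution
// post-burn-in time means.
// [[Rcpp::export]]
List cpp_integrate(const arma::mat& sc, const arma::vec& wEE,
                   const arma::vec& wEI, const arma::vec& wIE,
                   const arma::vec& sigma, double G, const List& nc,
                   double dt, int n_steps, int burn_steps, int record_stride,
                   bool with_noise, bool do_bold, const List& hc,
                   int tr_steps, int bw_stride, int rng_seed,
                   const arma::vec& sE0, const arma::vec& sI0) {
  NeuralConsts c = unpack_nc(nc);
  BWConsts h; if (do_bold) h = unpack_hc(hc);
  Xoshiro rng((uint64_t)rng_seed);
  arma::uword n = sE0.n_elem;
  arma::vec sE = sE0, sI = sI0;
  arma::vec rE(n), rI(n), dsE(n), dsI(n);
  arma::vec sqdt_sig = sigma * std::sqrt(dt);

  int n_ret = n_steps - burn_steps;
  int n_rec = (n_ret + record_stride - 1) / record_stride;
  arma::mat recSE(n_rec, n), recSI(n_rec, n), recRE(n_rec, n), recRI(n_rec, n);
  arma::vec mSE(n, arma::fill::zeros), mSI(n, arma::fill::zeros),
      mRE(n, arma::fill::zeros), mRI(n, arma::fill::zeros);

  arma::vec z(n, arma::fill::zeros), f(n, arma::fill::ones),
      v(n, arma::fill::ones), q(n, arma::fill::ones);
  int n_bold = do_bold ? n_ret / tr_steps : 0;
  arma::mat bold(std::max(n_bold, 0), n);
  arma::uword kb = 0;

  int rec = 0;
  for (int t = 0; t < n_steps; ++t) {
    drift(sc, wEE, wEI, wIE, G, c, sE, sI, rE, rI, dsE, dsI);
    int ret = t - burn_steps; // >= 0 once past burn-in
    if (ret >= 0) {
      mSE += sE; mSI += sI; mRE += rE; mRI += rI;
      if (ret % record_stride == 0) {
        recSE.row(rec) = sE.t(); recSI.row(rec) = sI.t();
        recRE.row(rec) = rE.t(); recRI.row(rec) = rI.t();
        ++rec;
      }
      if (do_bold) {
        // hemodynamics evolve on ~1 s time scales, so they are stepped on
        // a coarser substep than the neural state
        if (ret % bw_stride == 0) bw_step(h, dt * bw_stride, sE, z, f, v, q);
        if ((ret + 1) % tr_steps == 0 && kb < (arma::uword)n_bold)
          bold.row(kb++) = bw_readout(h, v, q).t();
      }
    }
    // Euler-Maruyama update; state clamped to [0, 1] (gating fractions)
    if (with_noise) {
      for (arma::uword i = 0; i < n; ++i) {
        sE[i] += dsE[i] * dt + sqdt_sig[i] * rng.normal();
        sI[i] += dsI[i] * dt + sqdt_sig[i] * rng.normal();
      }
    } else {
      sE += dsE * dt;
      sI += dsI * dt;
    }
    sE.clamp(0.0, 1.0);
    sI.clamp(0.0, 1.0);
    if (!sE.is_finite() || !sI.is_finite())
      stop("non-finite state at step %d", t + 1);
  }
  double inv = 1.0 / (double)n_ret;
  return List::create(
      _["s_e"] = recSE, _["s_i"] = recSI, _["r_e"] = recRE, _["r_i"] = recRI,
      _["mean_s_e"] = mSE * inv, _["mean_s_i"] = mSI * inv,
      _["mean_r_e"] = mRE * inv, _["mean_r_i"] = mRI * inv,
      _["bold"] = bold, _["final_s_e"] = sE, _["final_s_i"] = sI);
}

// Iterative feedback-inhibition calibration on the noise-free system.
// Each iteration integrates from the standard initial state (so the rate
// measured is that of the attractor a simulation actually reaches),
// averages r_E over the trailing segment, and nudges w_IE toward the
// target rate with a per-region adaptive gain (halved when the rate error
// changes sign, gently grown otherwise).
// [[Rcpp::export]]
List cpp_calibrate_fic(const arma::mat& sc, const arma::vec& wEE,
                       const arma::vec& wEI, double G, const List& nc,
                       double dt, int horizon_steps, int avg_steps,
                       double target, double tol, int max_iter, double eta,
                       double w_min, const arma::vec& wIE0,
                       const arma::vec& sE0, const arma::vec& sI0) {
  NeuralConsts c = unpack_nc(nc);
  arma::uword n = wEE.n_elem;
  arma::vec wIE = wIE0;
  arma::vec sE(n), sI(n);
  arma::vec rE(n), rI(n), dsE(n), dsI(n);
  arma::vec rbar(n, arma::fill::zeros);
  arma::vec gain(n); gain.fill(eta);
  arma::vec prev_err(n, arma::fill::zeros);
  arma::vec lo(n), hi(n);
  lo.fill(w_min); hi.fill(arma::datum::inf);
  int iter = 0;
  bool converged = false;
  for (iter = 1; iter <= max_iter; ++iter) {
    sE = sE0; sI = sI0;
    rbar.zeros();
    for (int t = 0; t < horizon_steps; ++t) {
      drift(sc, wEE, wEI, wIE, G, c, sE, sI, rE, rI, dsE, dsI);
      if (t >= horizon_steps - avg_steps) rbar += rE;
      sE += dsE * dt; sI += dsI * dt;
      sE.clamp(0.0, 1.0); sI.clamp(0.0, 1.0);
      if (!sE.is_finite() || !sI.is_finite())
        stop("non-finite state during calibration");
    }
    rbar /= (double)avg_steps;
    arma::vec err = rbar - target;
    if (arma::abs(err).max() <= tol) { converged = true; break; }
    // no root inside a collapsed bracket (discontinuous rate-weight map,
    // e.g. a collective network transition): give up early
    bool hopeless = false;
    for (arma::uword i = 0; i < n; ++i)
      if (std::isfinite(hi[i]) && hi[i] - lo[i] < 1e-4 &&
          std::fabs(err[i]) > 4.0 * tol) { hopeless = true; break; }
    if (hopeless) break;
    for (arma::uword i = 0; i < n; ++i) {
      // the attained rate is monotone decreasing in w_IE, so each
      // measurement updates a per-region bracket [lo, hi]; the freshest
      // value replaces the old edge because concurrent updates of other
      // regions shift the root
      if (err[i] > 0.0) {
        lo[i] = wIE[i];
        if (hi[i] <= lo[i]) hi[i] = arma::datum::inf;
      } else {
        hi[i] = wIE[i];
        if (lo[i] >= hi[i]) lo[i] = w_min;
      }
      if (iter > 1) {
        if (err[i] * prev_err[i] < 0.0) gain[i] *= 0.5;
        else gain[i] = std::min(gain[i] * 1.2, 10.0 * eta);
      }
      double step = gain[i] * err[i];
      if (step > 0.25) step = 0.25; else if (step < -0.25) step = -0.25;
      double prop = wIE[i] + step;
      if (std::isfinite(hi[i]) && (prop <= lo[i] || prop >= hi[i]))
        prop = 0.5 * (lo[i] + hi[i]); // bisection fallback inside bracket
      wIE[i] = std::max(w_min, prop);
    }
    prev_err = err;
  }
  return List::create(_["w_ie"] = wIE, _["rates"] = rbar,
                      _["iterations"] = std::min(iter, max_iter),
                      _["converged"] = converged,
                      _["final_s_e"] = sE, _["final_s_i"] = sI);
}
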