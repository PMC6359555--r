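// Core simulation kernels: model potentials, BAOAB Langevin stepping, and the
// full biased-trajectory loop (action-path accumulators, Gaussian hill history,
// gradient renormalization, restraint reweighting). Units: kJ/mol, nm, ps, amu.
// With these units 1 amu*nm^2/ps^2 == 1 kJ/mol, so KE = p^2/(2m) directly.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
#include <string>

using namespace Rcpp;

static const double KB = 0.0083144621; // kJ/mol/K

// ---------------------------------------------------------------------------
// RNG: mt19937_64 core with an explicit polar Box-Muller cache so that the
// draw sequence is fully determined by the seed (no library-dependent state).
// ---------------------------------------------------------------------------

static uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// named child streams derived from one master seed: toggling one stochastic
// component must not shift the draws of another
static uint64_t child_seed(uint64_t master, uint64_t stream) {
  return splitmix64(splitmix64(master + 1) ^ (0xA076BE5F1D2C3E4BULL * (stream + 1)));
}

struct Rng {
  std::mt19937_64 gen;
  bool has_cache;
  double cache;
  explicit Rng(uint64_t seed) : gen(seed), has_cache(false), cache(0.0) {}
  double unif() { // [0, 1)
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_cache) { has_cache = false; return cache; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    cache = v * f;
    has_cache = true;
    return u * f;
  }
};

// stream tags (documented in make_rng())
enum StreamTag { STREAM_THERMOSTAT = 1, STREAM_COUPLING = 2,
                 STREAM_ADAPTIVE = 3, STREAM_FIXTURES = 4, STREAM_INIT = 5 };

// [[Rcpp::export(name = ".cpp_make_rng")]]
SEXP cpp_make_rng(double seed, int stream) {
  uint64_t s = child_seed((uint64_t)seed, (uint64_t)stream);
  XPtr<Rng> ptr(new Rng(s), true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_rng_draw")]]
NumericVector cpp_rng_draw(SEXP rng_ptr, int n, bool normal) {
  XPtr<Rng> rng(rng_ptr);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = normal ? rng->norm() : rng->unif();
  return out;
}

// ---------------------------------------------------------------------------
// Model systems
// ---------------------------------------------------------------------------

enum SysId { SYS_DWELL1 = 0, SYS_DWELL2 = 1, SYS_MB = 2, SYS_TORSION = 3,
             SYS_CHAIN = 4 };

struct SysDef {
  int id;
  int n;    // particles
  int dim;  // per-particle dimension
  std::vector<double> mass; // per particle, amu
  std::vector<double> par;
};

static SysDef parse_sys(List s) {
  SysDef d;
  std::string nm = as<std::string>(s["name"]);
  d.n = as<int>(s["n_particles"]);
  d.dim = as<int>(s["dimension"]);
  d.mass = as<std::vector<double> >(s["masses"]);
  List p = s["parameters"];
  if (nm == "double_well_1d") {
    d.id = SYS_DWELL1; d.par = { as<double>(p["a"]), as<double>(p["b"]) };
  } else if (nm == "double_well_2d") {
    d.id = SYS_DWELL2; d.par = { as<double>(p["a"]), as<double>(p["b"]) };
  } else if (nm == "muller_brown") {
    d.id = SYS_MB;
  } else if (nm == "torsion_surface") {
    d.id = SYS_TORSION; d.par = { as<double>(p["A1"]), as<double>(p["A2"]) };
  } else if (nm == "bead_chain") {
    d.id = SYS_CHAIN;
    d.par = { as<double>(p["bond_k"]), as<double>(p["bond_r0"]),
              as<double>(p["repulsion_eps"]), as<double>(p["repulsion_sigma"]) };
  } else {
    stop("unknown system name: " + nm);
  }
  if ((int)d.mass.size() != d.n) stop("masses length must equal n_particles");
  return d;
}

// energy and gradient; g has length n*dim and is overwritten
static double potential(const SysDef& s, const double* q, double* g) {
  int dof = s.n * s.dim;
  double V = 0.0;
  for (int j = 0; j < dof; ++j) g[j] = 0.0;
  switch (s.id) {
  case SYS_DWELL1:
  case SYS_DWELL2: {
    double a = s.par[0], b = s.par[1];
    double b2 = b * b, b4 = b2 * b2;
    for (int j = 0; j < dof; ++j) {
      double x = q[j], r = x * x / b2 - 1.0;
      V += a * r * r;
      g[j] = 4.0 * a * x * (x * x - b2) / b4;
    }
    break;
  }
  case SYS_MB: {
    // Mueller-Brown surface, conventional coefficients, read in kJ/mol and nm
    static const double A[4]  = { -200.0, -100.0, -170.0, 15.0 };
    static const double aa[4] = { -1.0, -1.0, -6.5, 0.7 };
    static const double bb[4] = { 0.0, 0.0, 11.0, 0.6 };
    static const double cc[4] = { -10.0, -10.0, -6.5, 0.7 };
    static const double x0[4] = { 1.0, 0.0, -0.5, -1.0 };
    static const double y0[4] = { 0.0, 0.5, 1.5, 1.0 };
    double x = q[0], y = q[1];
    for (int j = 0; j < 4; ++j) {
      double dx = x - x0[j], dy = y - y0[j];
      double e = A[j] * std::exp(aa[j] * dx * dx + bb[j] * dx * dy + cc[j] * dy * dy);
      V += e;
      g[0] += e * (2.0 * aa[j] * dx + bb[j] * dy);
      g[1] += e * (bb[j] * dx + 2.0 * cc[j] * dy);
    }
    break;
  }
  case SYS_TORSION: {
    // separable periodic surface: 3-fold wells in phi, 2-fold in psi
    double A1 = s.par[0], A2 = s.par[1];
    double phi = q[0], psi = q[1];
    V = 0.5 * A1 * (1.0 + std::cos(3.0 * phi)) + 0.5 * A2 * (1.0 + std::cos(2.0 * psi));
    g[0] = -1.5 * A1 * std::sin(3.0 * phi);
    g[1] = -A2 * std::sin(2.0 * psi);
    break;
  }
  case SYS_CHAIN: {
    double k = s.par[0], r0 = s.par[1], eps = s.par[2], sig = s.par[3];
    double rc2 = sig * sig * std::pow(2.0, 1.0 / 3.0); // WCA cutoff squared
    int n = s.n;
    for (int i = 0; i + 1 < n; ++i) { // bonds
      const double* qi = q + 3 * i;
      const double* qj = q + 3 * (i + 1);
      double dx = qi[0] - qj[0], dy = qi[1] - qj[1], dz = qi[2] - qj[2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - r0;
      V += 0.5 * k * dr * dr;
      if (r > 0) {
        double f = k * dr / r;
        g[3 * i] += f * dx;     g[3 * i + 1] += f * dy;     g[3 * i + 2] += f * dz;
        g[3 * i + 3] -= f * dx; g[3 * i + 4] -= f * dy;     g[3 * i + 5] -= f * dz;
      }
    }
    for (int i = 0; i < n; ++i) { // purely repulsive, truncated-shifted LJ (WCA)
      for (int j = i + 2; j < n; ++j) {
        double dx = q[3 * i] - q[3 * j];
        double dy = q[3 * i + 1] - q[3 * j + 1];
        double dz = q[3 * i + 2] - q[3 * j + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rc2 || r2 == 0.0) continue;
        double s2 = sig * sig / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
        V += 4.0 * eps * (s12 - s6) + eps;
        double f = 24.0 * eps * (2.0 * s12 - s6) / r2; // -dV/dr / r
        g[3 * i] -= f * dx;     g[3 * i + 1] -= f * dy; g[3 * i + 2] -= f * dz;
        g[3 * j] += f * dx;     g[3 * j + 1] += f * dy; g[3 * j + 2] += f * dz;
      }
    }
    break;
  }
  default: stop("bad system id");
  }
  return V;
}

// [[Rcpp::export(name = ".cpp_potential")]]
List cpp_potential(List sys, NumericVector q) {
  SysDef s = parse_sys(sys);
  int dof = s.n * s.dim;
  if (q.size() != dof) stop("coordinate length does not match system");
  for (int j = 0; j < dof; ++j)
    if (!std::isfinite(q[j])) stop("non-finite coordinate");
  NumericVector g(dof);
  double V = potential(s, q.begin(), g.begin());
  return List::create(_["energy"] = V, _["gradient"] = g);
}

// ---------------------------------------------------------------------------
// BAOAB Langevin step. Total force = -grad V(q) - extra_gradient, with the
// extra gradient held fixed across the step (it is re-evaluated once per step
// by the caller). gamma = 0 reduces to velocity Verlet; the thermostat draw is
// consumed regardless so that toggling friction does not shift the stream.
// ---------------------------------------------------------------------------

static double baoab(const SysDef& s, double* q, double* p, const double* G,
                    double dt, double kT, double gamma, Rng& rng,
                    std::vector<double>& gbuf) {
  int dof = s.n * s.dim;
  potential(s, q, gbuf.data());
  for (int j = 0; j < dof; ++j) {
    double F = -gbuf[j] - G[j];
    if (!std::isfinite(F))
      stop("non-finite force encountered (component %d)", j + 1);
    p[j] += 0.5 * dt * F;
  }
  for (int j = 0; j < dof; ++j) q[j] += 0.5 * dt * p[j] / s.mass[j / s.dim];
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  for (int j = 0; j < dof; ++j) {
    double m = s.mass[j / s.dim];
    p[j] = c1 * p[j] + c2 * std::sqrt(m * kT) * rng.norm();
  }
  for (int j = 0; j < dof; ++j) q[j] += 0.5 * dt * p[j] / s.mass[j / s.dim];
  double V = potential(s, q, gbuf.data());
  for (int j = 0; j < dof; ++j) {
    double F = -gbuf[j] - G[j];
    if (!std::isfinite(F))
      stop("non-finite force encountered (component %d)", j + 1);
    p[j] += 0.5 * dt * F;
  }
  return V;
}

// [[Rcpp::export(name = ".cpp_langevin_step")]]
List cpp_langevin_step(List sys, NumericVector q, NumericVector p, double t,
                       NumericVector extra_gradient, double dt,
                       double temperature, double gamma, SEXP rng_ptr) {
  SysDef s = parse_sys(sys);
  int dof = s.n * s.dim;
  if (q.size() != dof || p.size() != dof) stop("state shape mismatch");
  if (extra_gradient.size() != dof) stop("extra_gradient shape mismatch");
  XPtr<Rng> rng(rng_ptr);
  std::vector<double> qq(q.begin(), q.end()), pp(p.begin(), p.end()),
    gbuf(dof);
  double V = baoab(s, qq.data(), pp.data(), extra_gradient.begin(), dt,
                   KB * temperature, gamma, *rng, gbuf);
  return List::create(_["q"] = NumericVector(qq.begin(), qq.end()),
                      _["p"] = NumericVector(pp.begin(), pp.end()),
                      _["t"] = t + dt, _["V"] = V);
}

// ---------------------------------------------------------------------------
// Small symmetric eigensolver (Jacobi) for per-atom covariance blocks (d <= 3)
// ---------------------------------------------------------------------------

static void jacobi_eigen(std::vector<double>& A, int d, std::vector<double>& evals,
                         std::vector<double>& evecs) {
  // A is d x d column-major, destroyed; evecs column-major
  evecs.assign(d * d, 0.0);
  for (int i = 0; i < d; ++i) evecs[i * d + i] = 1.0;
  for (int sweep = 0; sweep < 100; ++sweep) {
    double off = 0.0;
    for (int pcol = 0; pcol < d; ++pcol)
      for (int r = 0; r < pcol; ++r) off += A[pcol * d + r] * A[pcol * d + r];
    if (off < 1e-30) break;
    for (int pcol = 0; pcol < d; ++pcol) {
      for (int r = 0; r < pcol; ++r) {
        double apq = A[pcol * d + r];
        if (std::fabs(apq) < 1e-300) continue;
        double app = A[r * d + r], aqq = A[pcol * d + pcol];
        double theta = 0.5 * (aqq - app) / apq;
        double tsign = theta >= 0 ? 1.0 : -1.0;
        double tt = tsign / (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(tt * tt + 1.0), sn = tt * c;
        for (int k = 0; k < d; ++k) { // rotate rows/cols r and pcol
          double akr = A[r * d + k], akp = A[pcol * d + k];
          A[r * d + k] = c * akr - sn * akp;
          A[pcol * d + k] = sn * akr + c * akp;
        }
        for (int k = 0; k < d; ++k) {
          double akr = A[k * d + r], akp = A[k * d + pcol];
          A[k * d + r] = c * akr - sn * akp;
          A[k * d + pcol] = sn * akr + c * akp;
        }
        for (int k = 0; k < d; ++k) {
          double vkr = evecs[r * d + k], vkp = evecs[pcol * d + k];
          evecs[r * d + k] = c * vkr - sn * vkp;
          evecs[pcol * d + k] = sn * vkr + c * vkp;
        }
      }
    }
  }
  evals.resize(d);
  for (int i = 0; i < d; ++i) evals[i] = A[i * d + i];
}

// ---------------------------------------------------------------------------
// Biased trajectory loop
// ---------------------------------------------------------------------------

struct Restraint {
  std::vector<int> g1; // 0-based
  int g2;
  double d0;
};

struct HillStore {
  std::vector<double> centers;
  std::vector<double> weights; // effective W per hill
};

// hill force Phi = sum_c w_c (sigma - c)/dsig^2 exp(-(sigma - c)^2/(2 dsig^2))
static double hill_phi(const HillStore& h, double sigma, double dsig) {
  double phi = 0.0, d2 = dsig * dsig;
  size_t nc = h.centers.size();
  for (size_t c = 0; c < nc; ++c) {
    double dx = sigma - h.centers[c];
    phi += h.weights[c] * (dx / d2) * std::exp(-dx * dx / (2.0 * d2));
  }
  return phi;
}

static double hill_pot(const HillStore& h, double sigma, double dsig) {
  double v = 0.0, d2 = dsig * dsig;
  for (size_t c = 0; c < h.centers.size(); ++c) {
    double dx = sigma - h.centers[c];
    v += h.weights[c] * std::exp(-dx * dx / (2.0 * d2));
  }
  return v;
}

// [[Rcpp::export(name = ".cpp_run_trajectory")]]
List cpp_run_trajectory(List sys, NumericVector q0, NumericVector p0, double t0,
                        double dt, double temperature, double gamma, double seed,
                        Nullable<List> bias_, List restraints_, int n_steps,
                        int stride, bool debug) {
  SysDef s = parse_sys(sys);
  int n = s.n, dim = s.dim, dof = n * dim;
  if (q0.size() != dof || p0.size() != dof) stop("state shape mismatch");
  if (n_steps < 0) stop("n_steps must be >= 0");
  if (stride < 1) stop("stride must be >= 1");
  double kT = KB * temperature;

  Rng rng_thermo(child_seed((uint64_t)seed, STREAM_THERMOSTAT));
  Rng rng_xi(child_seed((uint64_t)seed, STREAM_COUPLING));
  Rng rng_zeta(child_seed((uint64_t)seed, STREAM_ADAPTIVE));

  // bias setup -------------------------------------------------------------
  bool has_bias = bias_.isNotNull();
  int NR = 0;
  double tau1 = 0, tau2 = 0, beta_md = 0, beta_pr = 0, eta_md = 0, eta_pr = 0,
    gamma_pp = 0, hill_w = 0, dsig_cfg = 0, delta_e = 0;
  bool well_tempered = false, use_pca = false;
  int pca_steps = 0;
  std::vector<int> m1, m2;         // window lengths (steps) per ladder index
  std::vector<double> tau1ik, tau2ik;
  if (has_bias) {
    List bias(bias_);
    NR = as<int>(bias["n_r"]);
    tau1 = as<double>(bias["tau1"]); tau2 = as<double>(bias["tau2"]);
    beta_md = as<double>(bias["beta_md"]); beta_pr = as<double>(bias["beta_prime"]);
    eta_md = as<double>(bias["eta_md"]); eta_pr = as<double>(bias["eta_prime"]);
    gamma_pp = as<double>(bias["gamma_pp"]);
    hill_w = as<double>(bias["hill_w"]); dsig_cfg = as<double>(bias["hill_dsigma"]);
    delta_e = as<double>(bias["delta_e"]);
    well_tempered = as<bool>(bias["well_tempered"]);
    use_pca = as<bool>(bias["use_pca"]);
    double pca_window = as<double>(bias["pca_window"]);
    if (NR < 1) stop("n_r must be >= 1");
    if (tau1 < dt || tau2 < dt) stop("bias periods must be >= dt");
    for (int i = 1; i <= NR; ++i) {
      int w1 = (int)std::lround(i * tau1 / dt);
      int w2 = (int)std::lround(i * tau2 / dt);
      if (w1 < 1 || w2 < 1) stop("bias window shorter than one step");
      m1.push_back(w1); m2.push_back(w2);
      tau1ik.push_back(w1 * dt); tau2ik.push_back(w2 * dt);
    }
    pca_steps = std::max(1, (int)std::lround(pca_window / dt));
  }

  // restraints ---------------------------------------------------------------
  std::vector<Restraint> res;
  for (int r = 0; r < restraints_.size(); ++r) {
    List rec = restraints_[r];
    Restraint R;
    R.g1 = as<std::vector<int> >(rec["group1"]);
    IntegerVector g2 = rec["group2"];
    if (g2.size() != 1) stop("group2 must contain exactly one atom");
    R.g2 = g2[0];
    R.d0 = as<double>(rec["d0"]);
    for (size_t a = 0; a < R.g1.size(); ++a)
      if (R.g1[a] < 0 || R.g1[a] >= n) stop("restraint atom index out of range");
    if (R.g2 < 0 || R.g2 >= n) stop("restraint atom index out of range");
    res.push_back(R);
  }
  int nres = (int)res.size();

  // bias state ---------------------------------------------------------------
  std::vector<double> vsum(has_bias ? (size_t)NR * dof : 0, 0.0);
  std::vector<double> g_ab(has_bias ? (size_t)NR * dof : 0, 0.0);
  std::vector<double> sigma(has_bias ? (size_t)NR * n : 0, 0.0);
  std::vector<HillStore> hills(has_bias ? (size_t)NR * n : 0);
  std::vector<double> chain(dof, 0.0); // current (p + dp) = p after the step
  double dsig = dsig_cfg > 0 ? dsig_cfg : -1.0; // -1: calibrate from 1st window
  double dsig_acc = 0.0;

  // PCA ring buffers (per component), row-major step x dof
  std::vector<double> buf_ab, buf_sg;
  std::vector<double> dir_ab(dof, 0.0), dir_sg(dof, 0.0);
  bool have_dir = false;
  int pca_fill = 0, pca_fallbacks = 0;
  if (has_bias && use_pca) {
    buf_ab.assign((size_t)pca_steps * dof, 0.0);
    buf_sg.assign((size_t)pca_steps * dof, 0.0);
  }

  // output -------------------------------------------------------------------
  int n_rec = n_steps / stride + 1;
  NumericMatrix Q(n_rec, dof), P(n_rec, dof);
  NumericVector Tm(n_rec), Vv(n_rec), KEv(n_rec);
  NumericVector Amd(n_rec), Apr(n_rec), Nab(n_rec), Nsg(n_rec);
  NumericMatrix Dres(n_rec, std::max(nres, 1));
  std::vector<double> hlog_t, hlog_i, hlog_k, hlog_c, hlog_w;
  // debug capture
  NumericMatrix dbg_G, dbg_ab, dbg_sg;
  NumericVector dbg_xi1, dbg_xi2, dbg_anorm;
  std::vector<double> zlog_step, zlog_i, zlog_k, zlog_z;
  if (debug) {
    dbg_G = NumericMatrix(n_steps, dof);
    dbg_ab = NumericMatrix(n_steps, dof);
    dbg_sg = NumericMatrix(n_steps, dof);
    dbg_xi1 = NumericVector(n_steps); dbg_xi2 = NumericVector(n_steps);
    dbg_anorm = NumericVector(n_steps);
  }

  std::vector<double> q(q0.begin(), q0.end()), p(p0.begin(), p0.end());
  std::vector<double> q_prev(q), p_prev(p);
  std::vector<double> gA(dof), gbuf(dof), G(dof, 0.0);
  std::vector<double> b_ab(dof), b_sg(dof), term_ab(dof), term_sg(dof);
  double t = t0;

  // record helper
  int rec_row = 0;
  double V0 = potential(s, q.data(), gbuf.data());
  double cur_amd = 0, cur_apr = 0, cur_nab = 0, cur_nsg = 0;
  auto record = [&](double V) {
    Tm[rec_row] = t;
    double ke = 0;
    for (int j = 0; j < dof; ++j) {
      Q(rec_row, j) = q[j]; P(rec_row, j) = p[j];
      ke += p[j] * p[j] / (2.0 * s.mass[j / dim]);
    }
    Vv[rec_row] = V; KEv[rec_row] = ke;
    Amd[rec_row] = cur_amd; Apr[rec_row] = cur_apr;
    Nab[rec_row] = cur_nab; Nsg[rec_row] = cur_nsg;
    for (int r = 0; r < nres; ++r) {
      // min-distance rule over group1
      double best = R_PosInf;
      const Restraint& R = res[r];
      for (size_t a = 0; a < R.g1.size(); ++a) {
        double d2 = 0;
        for (int c = 0; c < dim; ++c) {
          double dd = q[R.g1[a] * dim + c] - q[R.g2 * dim + c];
          d2 += dd * dd;
        }
        if (d2 < best) best = d2;
      }
      Dres(rec_row, r) = std::sqrt(best);
    }
    ++rec_row;
  };
  record(V0);

  for (int step = 1; step <= n_steps; ++step) {
    // ---- compute extra gradient from current bias machinery ----
    std::fill(G.begin(), G.end(), 0.0);
    cur_amd = cur_apr = cur_nab = cur_nsg = 0.0;
    if (has_bias) {
      // raw components
      for (int j = 0; j < dof; ++j) {
        double sab = 0;
        for (int i = 0; i < NR; ++i) sab += g_ab[(size_t)i * dof + j];
        b_ab[j] = sab;
      }
      double dsig_eff = dsig > 0 ? dsig : 1.0; // no hills exist before calibration
      for (int k = 0; k < n; ++k) {
        double phi_sum = 0.0;
        for (int i = 0; i < NR; ++i)
          phi_sum += hill_phi(hills[(size_t)i * n + k], sigma[(size_t)i * n + k],
                              dsig_eff);
        // gradient-level sigma bias: -Phi * (p + dp); the applied force
        // -grad then repels the path coordinate from deposited hills
        for (int c = 0; c < dim; ++c)
          b_sg[k * dim + c] = -phi_sum * chain[k * dim + c];
      }
      // PCA replacement of directions (per atom block), frozen between updates
      if (use_pca && dim > 1) {
        int row = (step - 1) % pca_steps;
        for (int j = 0; j < dof; ++j) {
          buf_ab[(size_t)row * dof + j] = b_ab[j];
          buf_sg[(size_t)row * dof + j] = b_sg[j];
        }
        if (pca_fill < pca_steps) ++pca_fill;
        if (pca_fill == pca_steps && step % pca_steps == 0) {
          have_dir = true;
          std::vector<double> C(dim * dim), evals, evecs, mean(dim);
          for (int comp = 0; comp < 2; ++comp) {
            const std::vector<double>& buf = comp == 0 ? buf_ab : buf_sg;
            std::vector<double>& dir = comp == 0 ? dir_ab : dir_sg;
            for (int k = 0; k < n; ++k) {
              for (int c = 0; c < dim; ++c) {
                double mu = 0;
                for (int r2 = 0; r2 < pca_steps; ++r2)
                  mu += buf[(size_t)r2 * dof + k * dim + c];
                mean[c] = mu / pca_steps;
              }
              double tot = 0;
              for (int a = 0; a < dim; ++a)
                for (int b2 = 0; b2 < dim; ++b2) {
                  double cv = 0;
                  for (int r2 = 0; r2 < pca_steps; ++r2)
                    cv += (buf[(size_t)r2 * dof + k * dim + a] - mean[a]) *
                          (buf[(size_t)r2 * dof + k * dim + b2] - mean[b2]);
                  C[b2 * dim + a] = cv / (pca_steps - 1);
                  if (a == b2) tot += C[b2 * dim + a];
                }
              if (!(tot > 0) || !std::isfinite(tot)) { // rank-deficient: raw
                ++pca_fallbacks;
                for (int c = 0; c < dim; ++c) dir[k * dim + c] = 0.0;
                continue;
              }
              std::vector<double> Cw(C);
              jacobi_eigen(Cw, dim, evals, evecs);
              int imin = 0;
              for (int e = 1; e < dim; ++e) if (evals[e] < evals[imin]) imin = e;
              double nrm = 0;
              for (int c = 0; c < dim; ++c) nrm += evecs[imin * dim + c] * evecs[imin * dim + c];
              nrm = std::sqrt(nrm);
              int first = 0;
              while (first < dim && evecs[imin * dim + first] == 0.0) ++first;
              double sgn = (first < dim && evecs[imin * dim + first] < 0) ? -1.0 : 1.0;
              for (int c = 0; c < dim; ++c)
                dir[k * dim + c] = sgn * evecs[imin * dim + c] / nrm;
            }
          }
        }
        if (have_dir) {
          for (int k = 0; k < n; ++k) {
            for (int comp = 0; comp < 2; ++comp) {
              std::vector<double>& dir = comp == 0 ? dir_ab : dir_sg;
              std::vector<double>& b = comp == 0 ? b_ab : b_sg;
              double dn = 0, bn = 0;
              for (int c = 0; c < dim; ++c) {
                dn += dir[k * dim + c] * dir[k * dim + c];
                bn += b[k * dim + c] * b[k * dim + c];
              }
              if (dn > 0) { // zero dir means fallback-to-raw for this atom
                bn = std::sqrt(bn);
                for (int c = 0; c < dim; ++c) b[k * dim + c] = dir[k * dim + c] * bn;
              }
            }
          }
        }
      }
      // coupling draws (one uniform per alpha per step, independent)
      double xi1 = rng_xi.unif(), xi2 = rng_xi.unif();
      cur_amd = eta_md * beta_md * (1.0 - xi1);
      cur_apr = eta_pr * beta_pr * (1.0 - xi2);
      double V_now = potential(s, q.data(), gA.data());
      (void)V_now;
      double anorm = 0, nab = 0, nsg = 0;
      for (int j = 0; j < dof; ++j) {
        anorm += gA[j] * gA[j]; nab += b_ab[j] * b_ab[j]; nsg += b_sg[j] * b_sg[j];
      }
      anorm = std::sqrt(anorm); nab = std::sqrt(nab); nsg = std::sqrt(nsg);
      if (!std::isfinite(anorm) || !std::isfinite(nab) || !std::isfinite(nsg))
        stop("non-finite gradient norm at step %d", step);
      cur_nab = nab; cur_nsg = nsg;
      double s_ab = (nab > 0) ? cur_apr * anorm / nab : 0.0;
      double s_sg = (nsg > 0) ? cur_apr * anorm / nsg : 0.0;
      for (int j = 0; j < dof; ++j) {
        term_ab[j] = b_ab[j] * s_ab;
        term_sg[j] = b_sg[j] * s_sg;
      }
      // restraint reweighting (Eq 13/33): per restrained atom, per component
      for (int r = 0; r < nres; ++r) {
        const Restraint& R = res[r];
        double best = R_PosInf; int a1 = R.g1[0];
        for (size_t a = 0; a < R.g1.size(); ++a) {
          double d2 = 0;
          for (int c = 0; c < dim; ++c) {
            double dd = q[R.g1[a] * dim + c] - q[R.g2 * dim + c];
            d2 += dd * dd;
          }
          if (d2 < best) { best = d2; a1 = R.g1[a]; }
        }
        double d12 = std::sqrt(best);
        if (d12 == 0.0) continue; // coincident atoms: skip this step
        double sgn = (d12 > R.d0) ? 1.0 : (d12 < R.d0 ? -1.0 : 0.0);
        std::vector<double> u(dim);
        for (int c = 0; c < dim; ++c)
          u[c] = (q[a1 * dim + c] - q[R.g2 * dim + c]) / d12;
        int atoms[2] = { a1, R.g2 };
        double dsgn[2] = { 1.0, -1.0 };
        for (int a = 0; a < 2; ++a) {
          int k = atoms[a];
          for (int comp = 0; comp < 2; ++comp) {
            std::vector<double>& term = comp == 0 ? term_ab : term_sg;
            double bn = 0, dp_ = 0;
            for (int c = 0; c < dim; ++c) {
              bn += term[k * dim + c] * term[k * dim + c];
              dp_ += term[k * dim + c] * u[c] * dsgn[a];
            }
            bn = std::sqrt(bn);
            double cosxi = bn > 0 ? dp_ / bn : 0.0;
            for (int c = 0; c < dim; ++c) term[k * dim + c] *= cosxi * sgn;
          }
        }
      }
      for (int j = 0; j < dof; ++j)
        G[j] = gA[j] * cur_amd + term_ab[j] + term_sg[j];
      if (debug) {
        dbg_xi1[step - 1] = xi1; dbg_xi2[step - 1] = xi2;
        dbg_anorm[step - 1] = anorm;
        for (int j = 0; j < dof; ++j) {
          dbg_G(step - 1, j) = G[j];
          dbg_ab(step - 1, j) = b_ab[j];
          dbg_sg(step - 1, j) = b_sg[j];
        }
      }
    }

    // ---- integrate one step ----
    q_prev = q; p_prev = p;
    double V = baoab(s, q.data(), p.data(), G.data(), dt, kT, gamma,
                     rng_thermo, gbuf);
    t = t0 + step * dt;

    // ---- post-step bias machinery update ----
    if (has_bias) {
      // dL(t) = (p + dp) o dq with p + dp = new momentum
      for (int j = 0; j < dof; ++j) chain[j] = p[j];
      for (int k = 0; k < n; ++k) {
        double sk = 0;
        for (int c = 0; c < dim; ++c) {
          double v = p[k * dim + c] * (q[k * dim + c] - q_prev[k * dim + c]);
          sk += v;
          for (int i = 0; i < NR; ++i) vsum[(size_t)i * dof + k * dim + c] += v;
        }
        for (int i = 0; i < NR; ++i) sigma[(size_t)i * n + k] += sk;
        if (dsig < 0) dsig_acc += sk;
      }
      // auto hill width: 5% of the sigma distance traversed per deposition
      // period, estimated once from the first tau2 window
      if (dsig < 0 && step == m2[0]) {
        // dsig_acc holds sigma increments summed over atoms and steps, so the
        // mean per-atom travel over the first window is dsig_acc / n
        double travel = std::fabs(dsig_acc / n);
        dsig = 0.05 * travel;
        if (!(dsig > 1e-8)) dsig = 1e-8;
      }
      for (int i = 0; i < NR; ++i) {
        if (step % m1[i] == 0) { // close adaptive window: freeze gradient
          for (int k = 0; k < n; ++k) {
            double zeta = rng_zeta.norm();
            if (debug) {
              zlog_step.push_back(step); zlog_i.push_back(i + 1);
              zlog_k.push_back(k + 1); zlog_z.push_back(zeta);
            }
            for (int c = 0; c < dim; ++c) {
              size_t idx = (size_t)i * dof + k * dim + c;
              g_ab[idx] = gamma_pp * zeta * vsum[idx] / tau1ik[i];
            }
          }
          for (int k = 0; k < n; ++k)
            for (int c = 0; c < dim; ++c)
              vsum[(size_t)i * dof + k * dim + c] = 0.0;
        }
        if (step % m2[i] == 0) { // deposit hills
          double dsig_eff = dsig > 0 ? dsig : 1e-8;
          for (int k = 0; k < n; ++k) {
            HillStore& h = hills[(size_t)i * n + k];
            double sg = sigma[(size_t)i * n + k];
            double w = hill_w;
            if (well_tempered && delta_e > 0)
              w = hill_w * std::exp(-hill_pot(h, sg, dsig_eff) / delta_e);
            h.centers.push_back(sg);
            h.weights.push_back(w);
            hlog_t.push_back(t); hlog_i.push_back(i + 1); hlog_k.push_back(k + 1);
            hlog_c.push_back(sg); hlog_w.push_back(w);
          }
        }
      }
    }

    if (step % stride == 0) record(V);
    if (step % 50000 == 0) Rcpp::checkUserInterrupt();
  }

  List hlog = List::create(_["t"] = hlog_t, _["i"] = hlog_i, _["k"] = hlog_k,
                           _["sigma_center"] = hlog_c, _["W_effective"] = hlog_w);
  List out = List::create(_["t"] = Tm, _["q"] = Q, _["p"] = P, _["V"] = Vv,
                          _["KE"] = KEv, _["alpha_md"] = Amd,
                          _["alpha_prime"] = Apr, _["bias_norm_ab"] = Nab,
                          _["bias_norm_sigma"] = Nsg, _["d_res"] = Dres,
                          _["n_restraints"] = nres, _["hills"] = hlog,
                          _["hill_dsigma"] = has_bias ? dsig : NA_REAL,
                          _["pca_fallbacks"] = pca_fallbacks);
  if (debug) {
    out["debug"] = List::create(
      _["xi_md"] = dbg_xi1, _["xi_prime"] = dbg_xi2, _["anorm"] = dbg_anorm,
      _["extra_gradient"] = dbg_G, _["bias_ab"] = dbg_ab, _["bias_sigma"] = dbg_sg,
      _["zeta_log"] = List::create(_["step"] = zlog_step, _["i"] = zlog_i,
                                   _["k"] = zlog_k, _["zeta"] = zlog_z));
  }
  return out;
}
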