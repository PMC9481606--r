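// Compiled core: overdamped Langevin propagation, the on-the-fly kernel bias
// (deposited every deposit_period steps, evaluated through a lattice between
// deposits) and unbiased first-passage sampling.  All randomness comes from a
// private mt19937_64 + Box-Muller stream so trajectories are bitwise
// reproducible for a given seed, independent of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() {
    // 53-bit mantissa, strictly inside (0,1)
    return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.28318530717958647692 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ---- analytic toy potentials -------------------------------------------
// id 1: double_well_1d   U = h (x^2 - 1)^2                params: h
// id 2: double_well_2d   U = h (x^2 - 1)^2 + ky y^2 / 2   params: h, ky
// id 3: binding_funnel_2d (z = exit coordinate, w = solvation gate)
//   U = -D exp(-z^2/(2 s0^2)) + H (1 + c (w-1)^2) exp(-(z-zb)^2/(2 sb^2))
//       + kappa w^2 / 2
//   params: D, s0, H, c, zb, sb, kappa
inline double pot_energy(int id, const double* p, const double* x) {
  switch (id) {
  case 1: { double q = x[0] * x[0] - 1.0; return p[0] * q * q; }
  case 2: { double q = x[0] * x[0] - 1.0;
            return p[0] * q * q + 0.5 * p[1] * x[1] * x[1]; }
  case 3: {
    double z = x[0], w = x[1];
    double D = p[0], s0 = p[1], H = p[2], c = p[3], zb = p[4], sb = p[5],
           kap = p[6];
    double g0 = std::exp(-0.5 * z * z / (s0 * s0));
    double dz = z - zb;
    double gb = std::exp(-0.5 * dz * dz / (sb * sb));
    double wm = w - 1.0;
    return -D * g0 + H * (1.0 + c * wm * wm) * gb + 0.5 * kap * w * w;
  }
  default: stop("unknown potential id");
  }
  return NA_REAL;
}

inline void pot_grad(int id, const double* p, const double* x, double* g) {
  switch (id) {
  case 1: { double q = x[0] * x[0] - 1.0; g[0] = 4.0 * p[0] * q * x[0]; return; }
  case 2: { double q = x[0] * x[0] - 1.0;
            g[0] = 4.0 * p[0] * q * x[0];
            g[1] = p[1] * x[1]; return; }
  case 3: {
    double z = x[0], w = x[1];
    double D = p[0], s0 = p[1], H = p[2], c = p[3], zb = p[4], sb = p[5],
           kap = p[6];
    double g0 = std::exp(-0.5 * z * z / (s0 * s0));
    double dz = z - zb;
    double gb = std::exp(-0.5 * dz * dz / (sb * sb));
    double wm = w - 1.0;
    double amp = H * (1.0 + c * wm * wm);
    g[0] = D * g0 * z / (s0 * s0) - amp * gb * dz / (sb * sb);
    g[1] = 2.0 * H * c * wm * gb + kap * w;
    return;
  }
  default: stop("unknown potential id");
  }
}

// ---- CV-space lattice carrying the instantaneous bias -------------------
// 1 or 2 CV dimensions; multilinear interpolation of V and of precomputed
// nodal gradients.  Outside the lattice V is clamped to the edge value and
// the corresponding force component is zero.
struct BiasGrid {
  int ncv = 0;
  std::vector<double> gmin, gmax, dx;
  std::vector<int> gn;
  std::vector<double> V;                  // n1 (*n2), column-major in dim 2
  std::vector<std::vector<double>> dV;    // per-dimension nodal gradient

  void init(int ncv_, const NumericVector& mn, const NumericVector& mx,
            const IntegerVector& nn) {
    ncv = ncv_;
    gmin.assign(mn.begin(), mn.begin() + ncv);
    gmax.assign(mx.begin(), mx.begin() + ncv);
    gn.assign(nn.begin(), nn.begin() + ncv);
    dx.resize(ncv);
    size_t tot = 1;
    for (int d = 0; d < ncv; ++d) {
      if (gn[d] < 2) stop("bias grid needs >= 2 nodes per dimension");
      dx[d] = (gmax[d] - gmin[d]) / (gn[d] - 1);
      tot *= (size_t)gn[d];
    }
    V.assign(tot, 0.0);
    dV.assign(ncv, std::vector<double>(tot, 0.0));
  }

  inline size_t idx(int i, int j) const {
    return ncv == 1 ? (size_t)i : (size_t)i + (size_t)gn[0] * (size_t)j;
  }

  void refresh_gradients() {
    if (ncv == 1) {
      int n = gn[0];
      for (int i = 0; i < n; ++i) {
        int lo = std::max(i - 1, 0), hi = std::min(i + 1, n - 1);
        dV[0][i] = (V[hi] - V[lo]) / ((hi - lo) * dx[0]);
      }
    } else {
      int n1 = gn[0], n2 = gn[1];
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          int lo = std::max(i - 1, 0), hi = std::min(i + 1, n1 - 1);
          dV[0][idx(i, j)] =
            (V[idx(hi, j)] - V[idx(lo, j)]) / ((hi - lo) * dx[0]);
          int lo2 = std::max(j - 1, 0), hi2 = std::min(j + 1, n2 - 1);
          dV[1][idx(i, j)] =
            (V[idx(i, hi2)] - V[idx(i, lo2)]) / ((hi2 - lo2) * dx[1]);
        }
    }
  }

  // value and gradient (in CV space) at s
  inline double eval(const double* s, double* grad) const {
    double t[2];
    int cell[2];
    bool outside[2] = {false, false};
    for (int d = 0; d < ncv; ++d) {
      double u = (s[d] - gmin[d]) / dx[d];
      if (u <= 0.0) { u = 0.0; outside[d] = s[d] < gmin[d]; }
      if (u >= gn[d] - 1) { u = gn[d] - 1; outside[d] = s[d] > gmax[d]; }
      int c = (int)std::floor(u);
      if (c > gn[d] - 2) c = gn[d] - 2;
      cell[d] = c;
      t[d] = u - c;
    }
    double val, g0, g1 = 0.0;
    if (ncv == 1) {
      int i = cell[0];
      val = V[i] * (1 - t[0]) + V[i + 1] * t[0];
      g0 = dV[0][i] * (1 - t[0]) + dV[0][i + 1] * t[0];
    } else {
      int i = cell[0], j = cell[1];
      double a = (1 - t[0]) * (1 - t[1]), b = t[0] * (1 - t[1]),
             c = (1 - t[0]) * t[1], d2 = t[0] * t[1];
      val = a * V[idx(i, j)] + b * V[idx(i + 1, j)] + c * V[idx(i, j + 1)] +
            d2 * V[idx(i + 1, j + 1)];
      g0 = a * dV[0][idx(i, j)] + b * dV[0][idx(i + 1, j)] +
           c * dV[0][idx(i, j + 1)] + d2 * dV[0][idx(i + 1, j + 1)];
      g1 = a * dV[1][idx(i, j)] + b * dV[1][idx(i + 1, j)] +
           c * dV[1][idx(i, j + 1)] + d2 * dV[1][idx(i + 1, j + 1)];
    }
    if (grad) {
      grad[0] = outside[0] ? 0.0 : g0;
      if (ncv == 2) grad[1] = outside[1] ? 0.0 : g1;
    }
    return val;
  }
};

// ---- on-the-fly kernel estimator (deposition bookkeeping) ---------------
struct OpesState {
  int ncv = 0;
  double gamma = 0, beta = 0, epsilon = 0, pref = 0;
  std::vector<double> sigma, norm_const;
  std::vector<double> c1, c2;   // kernel centers per CV dimension
  std::vector<double> w;        // kernel weights
  std::vector<double> punnorm;  // sum_j w_j G(s_k, s_j) at each center
  double sum_w = 0.0, Z = 1.0;
  double kernel_norm = 1.0;

  void init(int ncv_, double gamma_, double beta_, double eps_,
            const NumericVector& sig) {
    ncv = ncv_; gamma = gamma_; beta = beta_; epsilon = eps_;
    pref = (1.0 - 1.0 / gamma) / beta;
    sigma.assign(sig.begin(), sig.begin() + ncv);
    kernel_norm = 1.0;
    for (int d = 0; d < ncv; ++d)
      kernel_norm /= sigma[d] * 2.50662827463100050242;  // sqrt(2*pi)
  }

  inline double kernel(const double* s, size_t k) const {
    double e = 0.0;
    double d0 = (s[0] - c1[k]) / sigma[0];
    e += d0 * d0;
    if (ncv == 2) { double d1 = (s[1] - c2[k]) / sigma[1]; e += d1 * d1; }
    return e > 36.0 ? 0.0 : kernel_norm * std::exp(-0.5 * e);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_run_engine(int pot_id, NumericVector pot_params, NumericVector x0,
                    double dt, double kT, double friction, double n_steps_d,
                    int stride, double seed, NumericMatrix cvmat,
                    bool do_opes, double gamma, double epsilon,
                    NumericVector sigma, int deposit_period,
                    NumericVector grid_min, NumericVector grid_max,
                    IntegerVector grid_n, Nullable<NumericMatrix> excluded_,
                    Nullable<NumericVector> stop_, double domain_bound,
                    Nullable<List> static_bias_) {
  const int dim = x0.size();
  const int ncv = cvmat.nrow();
  if (cvmat.ncol() != dim) stop("cv map has wrong dimension");
  if (ncv > 2) stop("at most two collective variables are supported");
  const long long n_steps = (long long)n_steps_d;
  const double beta = 1.0 / kT;
  const double noise = std::sqrt(2.0 * kT * dt / friction);

  Rng rng((uint64_t)seed);

  // CV map rows
  std::vector<double> A(cvmat.begin(), cvmat.end());  // ncv x dim, col-major
  auto cv_of = [&](const double* x, double* s) {
    for (int r = 0; r < ncv; ++r) {
      double acc = 0.0;
      for (int c = 0; c < dim; ++c) acc += A[r + ncv * c] * x[c];
      s[r] = acc;
    }
  };

  // excluded region box (CV space)
  bool has_excl = excluded_.isNotNull();
  std::vector<double> exlo(ncv, 0), exhi(ncv, 0);
  if (has_excl) {
    NumericMatrix ex(excluded_);
    for (int d = 0; d < ncv; ++d) { exlo[d] = ex(0, d); exhi[d] = ex(1, d); }
  }
  auto in_excluded = [&](const double* s) {
    if (!has_excl) return false;
    for (int d = 0; d < ncv; ++d)
      if (s[d] < exlo[d] || s[d] > exhi[d]) return false;
    return true;
  };

  // stop predicate: (cv index [1-based], threshold, direction, dwell steps)
  bool has_stop = stop_.isNotNull();
  int stop_j = 0, dwell_steps = 1;
  double stop_c = 0, stop_dir = 1;
  if (has_stop) {
    NumericVector sp(stop_);
    stop_j = (int)sp[0] - 1;
    stop_c = sp[1];
    stop_dir = sp[2];
    dwell_steps = (int)sp[3];
    if (dwell_steps < 1) dwell_steps = 1;
  }

  // bias machinery
  BiasGrid grid;
  std::vector<double> kernel_sum;  // unnormalised kernel sum on lattice
  OpesState st;
  bool has_static = static_bias_.isNotNull();
  if (do_opes) {
    grid.init(ncv, grid_min, grid_max, grid_n);
    kernel_sum.assign(grid.V.size(), 0.0);
    st.init(ncv, gamma, beta, epsilon, sigma);
  } else if (has_static) {
    List sb(static_bias_);
    NumericVector mn = sb["grid_min"], mx = sb["grid_max"], vv = sb["V"];
    IntegerVector nn = sb["grid_n"];
    grid.init(ncv, mn, mx, nn);
    std::copy(vv.begin(), vv.end(), grid.V.begin());
    grid.refresh_gradients();
  }
  bool any_bias = do_opes || has_static;

  auto grid_positions = [&](int d, int i) { return grid.gmin[d] + i * grid.dx[d]; };

  auto rebuild_bias_lattice = [&]() {
    // V = pref * log( (S/sum_w)/Z + eps ) on every node
    size_t tot = grid.V.size();
    double inv = 1.0 / (st.sum_w * st.Z);
    for (size_t q = 0; q < tot; ++q)
      grid.V[q] = st.pref * std::log(kernel_sum[q] * inv + st.epsilon);
    grid.refresh_gradients();
  };

  auto add_kernel_to_lattice = [&](const double* cen, double weight) {
    if (ncv == 1) {
      int n = grid.gn[0];
      for (int i = 0; i < n; ++i) {
        double d0 = (grid_positions(0, i) - cen[0]) / st.sigma[0];
        double e = d0 * d0;
        if (e <= 36.0)
          kernel_sum[i] += weight * st.kernel_norm * std::exp(-0.5 * e);
      }
    } else {
      int n1 = grid.gn[0], n2 = grid.gn[1];
      for (int j = 0; j < n2; ++j) {
        double d1 = (grid_positions(1, j) - cen[1]) / st.sigma[1];
        double e1 = d1 * d1;
        if (e1 > 36.0) continue;
        for (int i = 0; i < n1; ++i) {
          double d0 = (grid_positions(0, i) - cen[0]) / st.sigma[0];
          double e = e1 + d0 * d0;
          if (e <= 36.0)
            kernel_sum[grid.idx(i, j)] +=
              weight * st.kernel_norm * std::exp(-0.5 * e);
        }
      }
    }
  };

  // outputs
  long long n_frames_cap = n_steps / stride + 2;
  std::vector<double> out_t; out_t.reserve(n_frames_cap);
  std::vector<double> out_x; out_x.reserve(n_frames_cap * dim);
  std::vector<double> out_s; out_s.reserve(n_frames_cap * ncv);
  std::vector<double> out_v; out_v.reserve(n_frames_cap);

  std::vector<double> x(x0.begin(), x0.end());
  double s[2] = {0, 0}, gpot[2] = {0, 0}, gbias[2] = {0, 0};
  cv_of(x.data(), s);

  double boost_sum = 0.0;
  long long boost_n = 0;
  const double floor_bias = st.pref * std::log(epsilon);
  long long n_dep = 0;
  int dwell = 0;
  bool exited = false;
  long long exit_step = -1;
  double t_exit = NA_REAL;

  auto record = [&](long long step, double vbias) {
    out_t.push_back(step * dt);
    for (int c = 0; c < dim; ++c) out_x.push_back(x[c]);
    for (int r = 0; r < ncv; ++r) out_s.push_back(s[r]);
    out_v.push_back(vbias);
    if (do_opes) {
      double fl = (n_dep > 0) ? floor_bias : 0.0;
      boost_sum += std::exp(beta * (vbias - fl));
    } else {
      boost_sum += std::exp(beta * vbias);
    }
    boost_n += 1;
  };

  double vcur = any_bias ? grid.eval(s, nullptr) : 0.0;
  if (do_opes) vcur = 0.0;  // V0 = 0 before any deposit
  record(0, vcur);

  for (long long step = 1; step <= n_steps; ++step) {
    // forces at current position
    pot_grad(pot_id, pot_params.begin(), x.data(), gpot);
    double fbias_x[2] = {0, 0};
    if (any_bias && (!do_opes || n_dep > 0)) {
      vcur = grid.eval(s, gbias);
      for (int c = 0; c < dim; ++c) {
        double acc = 0.0;
        for (int r = 0; r < ncv; ++r) acc += A[r + ncv * c] * gbias[r];
        fbias_x[c] = -acc;
      }
    } else {
      vcur = 0.0;
    }
    for (int c = 0; c < dim; ++c) {
      x[c] += (-(gpot[c]) + fbias_x[c]) * dt / friction + noise * rng.norm();
      if (!std::isfinite(x[c]) || std::fabs(x[c]) > domain_bound)
        stop("trajectory diverged at step " + std::to_string(step) +
             " (|x| exceeds the domain bound)");
    }
    cv_of(x.data(), s);

    // deposit
    if (do_opes && deposit_period > 0 && step % deposit_period == 0 &&
        step < n_steps) {
      if (!in_excluded(s)) {
        double vdep = (n_dep > 0) ? grid.eval(s, nullptr) : 0.0;
        double weight = std::exp(beta * vdep);
        // bookkeeping for Z at centers
        size_t n_old = st.w.size();
        std::vector<double> addv(n_old);
        for (size_t k = 0; k < n_old; ++k) {
          double e = 0.0;
          double d0 = (st.c1[k] - s[0]) / st.sigma[0];
          e += d0 * d0;
          if (ncv == 2) { double d1 = (st.c2[k] - s[1]) / st.sigma[1]; e += d1 * d1; }
          addv[k] = e > 36.0 ? 0.0 : weight * st.kernel_norm * std::exp(-0.5 * e);
        }
        for (size_t k = 0; k < n_old; ++k) st.punnorm[k] += addv[k];
        st.c1.push_back(s[0]);
        st.c2.push_back(ncv == 2 ? s[1] : 0.0);
        st.w.push_back(weight);
        st.sum_w += weight;
        double cen[2] = {s[0], ncv == 2 ? s[1] : 0.0};
        double pn = 0.0;
        for (size_t k = 0; k < st.w.size(); ++k) pn += st.w[k] * st.kernel(cen, k);
        st.punnorm.push_back(pn);
        double acc = 0.0;
        for (size_t k = 0; k < st.punnorm.size(); ++k)
          acc += st.punnorm[k] / st.sum_w;
        st.Z = acc / st.punnorm.size();
        add_kernel_to_lattice(cen, weight);
        rebuild_bias_lattice();
        n_dep += 1;
      }
    }

    bool at_stride = (step % stride == 0);
    double vrec = 0.0;
    if (any_bias && (!do_opes || n_dep > 0)) vrec = grid.eval(s, nullptr);

    // stop predicate with commitment dwell
    if (has_stop) {
      double val = s[stop_j];
      bool hit = stop_dir > 0 ? (val > stop_c) : (val < stop_c);
      if (hit) {
        dwell += 1;
        if (dwell >= dwell_steps) {
          exited = true;
          exit_step = step - (dwell_steps - 1);
          t_exit = exit_step * dt;
          record(step, vrec);
          break;
        }
      } else {
        dwell = 0;
      }
    }
    if (at_stride) record(step, vrec);
  }

  long long nf = (long long)out_t.size();
  NumericVector rt(nf), rv(nf);
  NumericMatrix rx(nf, dim), rs(nf, ncv);
  for (long long i = 0; i < nf; ++i) {
    rt[i] = out_t[i];
    rv[i] = out_v[i];
    for (int c = 0; c < dim; ++c) rx(i, c) = out_x[i * dim + c];
    for (int r = 0; r < ncv; ++r) rs(i, r) = out_s[i * ncv + r];
  }
  List res = List::create(
    _["time"] = rt, _["x"] = rx, _["cv"] = rs, _["bias"] = rv,
    _["exited"] = exited, _["exit_step"] = (double)exit_step,
    _["t_exit"] = t_exit, _["boost_mean"] = boost_n ? boost_sum / boost_n : 1.0,
    _["n_frames"] = (double)boost_n);
  if (do_opes) {
    size_t nk = st.w.size();
    NumericMatrix centers(nk, ncv);
    NumericVector weights(nk);
    for (size_t k = 0; k < nk; ++k) {
      centers(k, 0) = st.c1[k];
      if (ncv == 2) centers(k, 1) = st.c2[k];
      weights[k] = st.w[k];
    }
    res["centers"] = centers;
    res["weights"] = weights;
    res["sum_w"] = st.sum_w;
    res["Z"] = st.Z;
    res["n_deposits"] = (double)n_dep;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_first_passage(int pot_id, NumericVector pot_params, NumericVector x0,
                       double dt, double kT, double friction,
                       NumericMatrix cvmat, NumericVector stop_spec,
                       double max_steps_d, double seed, int n_events) {
  const int dim = x0.size();
  const int ncv = cvmat.nrow();
  const long long max_steps = (long long)max_steps_d;
  const double noise = std::sqrt(2.0 * kT * dt / friction);
  Rng rng((uint64_t)seed);
  std::vector<double> A(cvmat.begin(), cvmat.end());
  int stop_j = (int)stop_spec[0] - 1;
  double stop_c = stop_spec[1], stop_dir = stop_spec[2];
  int dwell_steps = (int)stop_spec[3];
  if (dwell_steps < 1) dwell_steps = 1;

  NumericVector times(n_events);
  LogicalVector done(n_events);
  long long budget = max_steps;
  std::vector<double> x(dim), gpot(dim);
  for (int ev = 0; ev < n_events; ++ev) {
    std::copy(x0.begin(), x0.end(), x.begin());
    int dwell = 0;
    bool hit_ev = false;
    long long step = 0;
    while (budget > 0) {
      ++step; --budget;
      pot_grad(pot_id, pot_params.begin(), x.data(), gpot.data());
      for (int c = 0; c < dim; ++c)
        x[c] += -gpot[c] * dt / friction + noise * rng.norm();
      double s = 0.0;
      for (int c = 0; c < dim; ++c) s += A[stop_j + ncv * c] * x[c];
      bool hit = stop_dir > 0 ? (s > stop_c) : (s < stop_c);
      if (hit) {
        if (++dwell >= dwell_steps) {
          times[ev] = (step - (dwell_steps - 1)) * dt;
          done[ev] = true;
          hit_ev = true;
          break;
        }
      } else dwell = 0;
    }
    if (!hit_ev) {
      times[ev] = NA_REAL;
      done[ev] = false;
      break;  // budget exhausted
    }
  }
  return List::create(_["times"] = times, _["completed"] = done,
                      _["steps_left"] = (double)budget);
}

// [[Rcpp::export]]
NumericVector cpp_pot_energy(int pot_id, NumericVector pot_params,
                             NumericMatrix x) {
  int n = x.nrow(), dim = x.ncol();
  NumericVector out(n);
  std::vector<double> xi(dim);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < dim; ++c) xi[c] = x(i, c);
    out[i] = pot_energy(pot_id, pot_params.begin(), xi.data());
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_pot_grad(int pot_id, NumericVector pot_params,
                           NumericMatrix x) {
  int n = x.nrow(), dim = x.ncol();
  NumericMatrix out(n, dim);
  std::vector<double> xi(dim), gi(dim);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < dim; ++c) xi[c] = x(i, c);
    pot_grad(pot_id, pot_params.begin(), xi.data(), gi.data());
    for (int c = 0; c < dim; ++c) out(i, c) = gi[c];
  }
  return out;
}
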