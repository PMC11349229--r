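#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Built-in toy potentials, selected by integer code so the integrator loop
// stays in compiled code.  Energies in kT = 1 reduced units.
//   1: isotropic harmonic, U = 0.5 * k * |x|^2,            params = (k)
//   2: 1-D double well,    U = h * (x^2 - 1)^2,            params = (h)
//   3: periodic 1-D double well on an angle,
//      U = 0.5 * b * (1 - cos(2 * (x - t0))), minima at t0 and t0 + pi,
//      coordinate wrapped into (-pi, pi],                  params = (b, t0)
//   4: 2-D double well,    U = h * (x^2-1)^2 + 0.5*k*y^2,  params = (h, k)

static inline double pot_energy(int code, const std::vector<double> &par,
                                const double *x, int dim) {
  switch (code) {
  case 1: {
    double s = 0.0;
    for (int d = 0; d < dim; ++d) s += x[d] * x[d];
    return 0.5 * par[0] * s;
  }
  case 2: {
    double q = x[0] * x[0] - 1.0;
    return par[0] * q * q;
  }
  case 3:
    return 0.5 * par[0] * (1.0 - std::cos(2.0 * (x[0] - par[1])));
  case 4: {
    double q = x[0] * x[0] - 1.0;
    return par[0] * q * q + 0.5 * par[1] * x[1] * x[1];
  }
  default:
    stop("unknown potential code");
  }
  return 0.0;
}

static inline void pot_grad(int code, const std::vector<double> &par,
                            const double *x, int dim, double *g) {
  switch (code) {
  case 1:
    for (int d = 0; d < dim; ++d) g[d] = par[0] * x[d];
    break;
  case 2:
    g[0] = 4.0 * par[0] * x[0] * (x[0] * x[0] - 1.0);
    break;
  case 3:
    g[0] = par[0] * std::sin(2.0 * (x[0] - par[1]));
    break;
  case 4:
    g[0] = 4.0 * par[0] * x[0] * (x[0] * x[0] - 1.0);
    g[1] = par[1] * x[1];
    break;
  default:
    stop("unknown potential code");
  }
}

static inline double wrap_angle(double a) {
  a -= 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI));  // [-pi, pi)
  if (a <= -M_PI) a = M_PI;
  return a;
}

// [[Rcpp::export(name = ".langevin_cpp")]]
NumericMatrix langevin_cpp(int code, NumericVector params, NumericVector x0,
                           int n_steps, double dt, double friction,
                           double kT, int stride, double bound) {
  int dim = x0.size();
  std::vector<double> par(params.begin(), params.end());
  std::vector<double> x(x0.begin(), x0.end()), g(dim);
  bool periodic = (code == 3);

  int n_rec = n_steps / stride + 1;
  NumericMatrix out(n_rec, dim + 1);
  out(0, 0) = 0.0;
  for (int d = 0; d < dim; ++d) out(0, d + 1) = x[d];

  double amp = std::sqrt(2.0 * dt * kT / friction);
  int row = 1;
  for (int step = 1; step <= n_steps; ++step) {
    pot_grad(code, par, x.data(), dim, g.data());
    for (int d = 0; d < dim; ++d) {
      x[d] += -g[d] * dt / friction + amp * norm_rand();
      if (periodic) x[d] = wrap_angle(x[d]);
      if (std::abs(x[d]) > bound)
        stop("langevin trajectory diverged at step %d", step);
    }
    if (step % stride == 0) {
      out(row, 0) = step * dt;
      for (int d = 0; d < dim; ++d) out(row, d + 1) = x[d];
      ++row;
    }
  }
  return out;
}

struct ToyCV {
  int type;                     // 0 = coordinate, 1 = affine sin/cos
  int idx;                      // coordinate index (type 0)
  double offset;
  std::vector<double> bsin, bcos;
};

static inline double cv_value(const ToyCV &cv, const double *x) {
  if (cv.type == 0) return x[cv.idx];
  double v = cv.offset;
  for (size_t d = 0; d < cv.bsin.size(); ++d)
    v += cv.bsin[d] * std::sin(x[d]) + cv.bcos[d] * std::cos(x[d]);
  return v;
}

static inline void cv_grad(const ToyCV &cv, const double *x, int dim,
                           double *g) {
  for (int d = 0; d < dim; ++d) g[d] = 0.0;
  if (cv.type == 0) {
    g[cv.idx] = 1.0;
  } else {
    for (size_t d = 0; d < cv.bsin.size(); ++d)
      g[d] = cv.bsin[d] * std::cos(x[d]) - cv.bcos[d] * std::sin(x[d]);
  }
}

// [[Rcpp::export(name = ".wt_metad_cpp")]]
List wt_metad_cpp(int code, NumericVector params, NumericVector x0,
                  int n_steps, double dt, double friction, double kT,
                  int stride, int pace, double height, NumericVector widths,
                  double biasfactor, List cv_list, double bound) {
  int dim = x0.size();
  int ncv = cv_list.size();
  if (widths.size() != ncv) stop("one Gaussian width per CV is required");
  std::vector<double> par(params.begin(), params.end());
  std::vector<double> x(x0.begin(), x0.end()), g(dim), gc(dim);
  bool periodic = (code == 3);

  std::vector<ToyCV> cvs(ncv);
  for (int k = 0; k < ncv; ++k) {
    List c = cv_list[k];
    ToyCV tc;
    tc.type = as<int>(c["type"]);
    if (tc.type == 0) {
      tc.idx = as<int>(c["idx"]) - 1;   // R is 1-based
      if (tc.idx < 0 || tc.idx >= dim) stop("CV coordinate index out of range");
    } else {
      tc.offset = as<double>(c["offset"]);
      NumericVector bs = c["bsin"], bc = c["bcos"];
      if (bs.size() != dim || bc.size() != dim)
        stop("sin/cos CV coefficient length must equal the dimension");
      tc.bsin.assign(bs.begin(), bs.end());
      tc.bcos.assign(bc.begin(), bc.end());
    }
    cvs[k] = tc;
  }

  // deposited hills: centers (ncv per hill), heights, times
  std::vector<double> hc, hh, ht;
  std::vector<double> s(ncv), dvds(ncv);
  std::vector<double> inv2w2(ncv);
  for (int k = 0; k < ncv; ++k) inv2w2[k] = 1.0 / (2.0 * widths[k] * widths[k]);

  int n_rec = n_steps / stride + 1;
  // time, s_1..s_ncv, x_1..x_dim, bias
  NumericMatrix colvar(n_rec, ncv + dim + 2);
  int row = 0;

  double amp = std::sqrt(2.0 * dt * kT / friction);
  double gamma_fac = (biasfactor - 1.0) * kT;

  for (int step = 0; step <= n_steps; ++step) {
    for (int k = 0; k < ncv; ++k) s[k] = cv_value(cvs[k], x.data());

    // bias energy and its gradient in CV space
    double V = 0.0;
    for (int k = 0; k < ncv; ++k) dvds[k] = 0.0;
    size_t nh = hh.size();
    for (size_t i = 0; i < nh; ++i) {
      double e = 0.0;
      for (int k = 0; k < ncv; ++k) {
        double d = s[k] - hc[i * ncv + k];
        e += d * d * inv2w2[k];
      }
      e = hh[i] * std::exp(-e);
      V += e;
      for (int k = 0; k < ncv; ++k)
        dvds[k] += -e * (s[k] - hc[i * ncv + k]) * 2.0 * inv2w2[k];
    }

    if (step % stride == 0) {
      colvar(row, 0) = step * dt;
      for (int k = 0; k < ncv; ++k) colvar(row, k + 1) = s[k];
      for (int d = 0; d < dim; ++d) colvar(row, ncv + 1 + d) = x[d];
      colvar(row, ncv + dim + 1) = V;
      ++row;
    }

    // well-tempered deposition (after recording so COLVAR sees pre-hill bias)
    if (step > 0 && step % pace == 0) {
      double hdep = height * std::exp(-V / gamma_fac);
      for (int k = 0; k < ncv; ++k) hc.push_back(s[k]);
      hh.push_back(hdep);
      ht.push_back(step * dt);
      // the new hill acts immediately; centered at s its force is zero
    }

    if (step == n_steps) break;

    pot_grad(code, par, x.data(), dim, g.data());
    // total force: -dU/dx - sum_k dV/ds_k * ds_k/dx
    for (int k = 0; k < ncv; ++k) {
      cv_grad(cvs[k], x.data(), dim, gc.data());
      for (int d = 0; d < dim; ++d) g[d] += dvds[k] * gc[d];
    }
    for (int d = 0; d < dim; ++d) {
      x[d] += -g[d] * dt / friction + amp * norm_rand();
      if (periodic) x[d] = wrap_angle(x[d]);
      if (std::abs(x[d]) > bound)
        stop("metadynamics trajectory diverged at step %d", step + 1);
    }
  }

  int nhill = hh.size();
  NumericMatrix hills(nhill, ncv + 2);
  for (int i = 0; i < nhill; ++i) {
    hills(i, 0) = ht[i];
    for (int k = 0; k < ncv; ++k) hills(i, k + 1) = hc[i * ncv + k];
    hills(i, ncv + 1) = hh[i];
  }
  return List::create(_["colvar"] = colvar, _["hills"] = hills);
}

// [[Rcpp::export(name = ".pot_energy_cpp")]]
NumericVector pot_energy_cpp(int code, NumericVector params, NumericMatrix x) {
  std::vector<double> par(params.begin(), params.end());
  int n = x.nrow(), dim = x.ncol();
  NumericVector out(n);
  std::vector<double> xi(dim);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < dim; ++d) xi[d] = x(i, d);
    out[i] = pot_energy(code, par, xi.data(), dim);
  }
  return out;
}
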