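#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Method-of-lines right-hand sides for the two reaction-diffusion models on a
// closed rectangular grid with zero-flux Neumann boundaries (mirrored ghost
// nodes). Vertex order is row-major with y as the outer index:
// idx = iy*nx + ix, coordinates (ix*h, iy*h).

namespace {

inline void reaction_terms(int model, double alpha, double beta, double sigma,
                           const double* u, const double* v, int n,
                           double* fu, double* fv) {
  if (model == 0) { // CIMA; the sigma prefactor of the inhibitor is folded in
    for (int i = 0; i < n; ++i) {
      double q = 1.0 + u[i] * u[i];
      fu[i] = alpha - u[i] - 4.0 * u[i] * v[i] / q;
      fv[i] = sigma * (beta * u[i] - beta * u[i] * v[i] / q);
    }
  } else { // Schnakenberg
    for (int i = 0; i < n; ++i) {
      double q = u[i] * u[i];
      fu[i] = alpha - u[i] + q * v[i];
      fv[i] = beta - q * v[i];
    }
  }
}

// 5-point Laplacian with mirrored ghost nodes, scaled by d/h^2.
inline void laplacian(const double* w, int nx, int ny, double dh2, double* out) {
  for (int iy = 0; iy < ny; ++iy) {
    const double* row = w + (size_t)iy * nx;
    const double* rs = (iy > 0) ? row - nx : row + nx;      // south (mirror)
    const double* rn = (iy < ny - 1) ? row + nx : row - nx;  // north (mirror)
    double* o = out + (size_t)iy * nx;
    for (int ix = 0; ix < nx; ++ix) {
      double wl = (ix > 0) ? row[ix - 1] : row[ix + 1];
      double wr = (ix < nx - 1) ? row[ix + 1] : row[ix - 1];
      o[ix] = dh2 * (wl + wr + rs[ix] + rn[ix] - 4.0 * row[ix]);
    }
  }
}

struct RDSystem {
  int model, nx, ny, n;
  double alpha, beta, delta, sigma, h;
  double du, dv;
  bool react;
  std::vector<double> fu, fv, lu, lv;

  RDSystem(int model_, int nx_, int ny_, double h_, double alpha_,
           double beta_, double delta_, double sigma_, bool react_)
      : model(model_), nx(nx_), ny(ny_), n(nx_ * ny_), alpha(alpha_),
        beta(beta_), delta(delta_), sigma(sigma_), h(h_), react(react_),
        fu(n), fv(n), lu(n), lv(n) {
    du = 1.0;
    dv = (model == 0) ? sigma * delta : delta;
  }

  // full RHS into (ru, rv)
  void rhs(const double* u, const double* v, double* ru, double* rv) {
    laplacian(u, nx, ny, du / (h * h), lu.data());
    laplacian(v, nx, ny, dv / (h * h), lv.data());
    if (react) {
      reaction_terms(model, alpha, beta, sigma, u, v, n, fu.data(), fv.data());
      for (int i = 0; i < n; ++i) { ru[i] = lu[i] + fu[i]; rv[i] = lv[i] + fv[i]; }
    } else {
      for (int i = 0; i < n; ++i) { ru[i] = lu[i]; rv[i] = lv[i]; }
    }
  }
};

// Tridiagonal solver for (I - a*L1d) with mirrored-ghost Neumann Laplacian:
// diagonal 1+2a everywhere, off-diagonals -a except -2a adjacent to the two
// boundary rows. Forward-elimination coefficients are precomputed once.
struct Thomas {
  int n;
  double a;
  std::vector<double> cp;   // modified super-diagonal
  std::vector<double> inv;  // 1 / pivot
  std::vector<double> sub;  // sub-diagonal entries

  void init(int n_, double a_) {
    n = n_; a = a_;
    cp.assign(n, 0.0); inv.assign(n, 0.0); sub.assign(n, 0.0);
    std::vector<double> sup(n, -a);
    sup[0] = -2.0 * a;
    for (int i = 1; i < n; ++i) sub[i] = (i == n - 1) ? -2.0 * a : -a;
    double b = 1.0 + 2.0 * a;
    inv[0] = 1.0 / b;
    cp[0] = sup[0] * inv[0];
    for (int i = 1; i < n; ++i) {
      double piv = b - sub[i] * cp[i - 1];
      inv[i] = 1.0 / piv;
      if (i < n - 1) cp[i] = sup[i] * inv[i];
    }
  }

  // solve in place over a strided vector x[0], x[s], ...
  void solve(double* x, int s) const {
    x[0] *= inv[0];
    for (int i = 1; i < n; ++i)
      x[(size_t)i * s] = (x[(size_t)i * s] - sub[i] * x[(size_t)(i - 1) * s]) * inv[i];
    for (int i = n - 2; i >= 0; --i)
      x[(size_t)i * s] -= cp[i] * x[(size_t)(i + 1) * s];
  }
};

inline double maxabs(const double* x, int n) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) { double ax = std::fabs(x[i]); if (ax > m) m = ax; }
  return m;
}

inline bool anybad(const double* x, int n) {
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e8) return true;
  return false;
}

} // namespace

// [[Rcpp::export(name = ".rd_rhs_cpp")]]
List rd_rhs_cpp(NumericVector u, NumericVector v, int nx, int ny, double h,
                int model, double alpha, double beta, double delta,
                double sigma, bool react) {
  RDSystem sys(model, nx, ny, h, alpha, beta, delta, sigma, react);
  NumericVector ru(u.size()), rv(v.size());
  sys.rhs(u.begin(), v.begin(), ru.begin(), rv.begin());
  return List::create(_["du"] = ru, _["dv"] = rv);
}

// Semi-implicit scheme: Peaceman-Rachford ADI for the diffusion operator
// (unconditionally stable) with the reaction terms advanced explicitly inside
// the two half-steps. Fixed dt, steady-state detection on the sup-norm of the
// full right-hand side every `check_every` time units.
// [[Rcpp::export(name = ".rd_integrate_imex_cpp")]]
List rd_integrate_imex_cpp(NumericVector u0, NumericVector v0, int nx, int ny,
                           double h, int model, double alpha, double beta,
                           double delta, double sigma, double tau_end,
                           double dt, double steady_tol, double check_every,
                           bool react) {
  RDSystem sys(model, nx, ny, h, alpha, beta, delta, sigma, react);
  int n = sys.n;
  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> us(n), vs(n), ru(n), rv(n);

  double au_x, av_x; // dt/2 * d / h^2 per species
  Thomas tux, tuy, tvx, tvy;
  auto setup = [&](double dt_) {
    au_x = 0.5 * dt_ * sys.du / (h * h);
    av_x = 0.5 * dt_ * sys.dv / (h * h);
    tux.init(nx, au_x); tuy.init(ny, au_x);
    tvx.init(nx, av_x); tvy.init(ny, av_x);
  };
  setup(dt);

  double t = 0.0, next_check = check_every;
  std::string status = "tau_end_reached";
  double deriv = NA_REAL;

  while (t < tau_end - 1e-12) {
    double step = std::min(dt, tau_end - t);
    bool resized = step != dt;
    if (resized) setup(step);

    // half-step 1: implicit in x, explicit in y + reaction at (u, v)
    laplacian(u.data(), nx, ny, sys.du / (h * h), sys.lu.data());
    laplacian(v.data(), nx, ny, sys.dv / (h * h), sys.lv.data());
    if (react)
      reaction_terms(model, alpha, beta, sigma, u.data(), v.data(), n,
                     sys.fu.data(), sys.fv.data());
    else {
      std::fill(sys.fu.begin(), sys.fu.end(), 0.0);
      std::fill(sys.fv.begin(), sys.fv.end(), 0.0);
    }
    double hdt = 0.5 * step;
    // rhs = w + hdt*(Ly w + R); the y-part is full Laplacian minus x-part
    auto half1 = [&](std::vector<double>& w, std::vector<double>& wstar,
                     const std::vector<double>& lap, const std::vector<double>& R,
                     double dcoef, Thomas& tx) {
      double dh2 = dcoef / (h * h);
      for (int iy = 0; iy < ny; ++iy) {
        size_t off = (size_t)iy * nx;
        for (int ix = 0; ix < nx; ++ix) {
          size_t i = off + ix;
          double wl = (ix > 0) ? w[i - 1] : w[i + 1];
          double wr = (ix < nx - 1) ? w[i + 1] : w[i - 1];
          double lx = dh2 * (wl + wr - 2.0 * w[i]);
          double ly = lap[i] - lx;
          wstar[i] = w[i] + hdt * (ly + R[i]);
        }
      }
      for (int iy = 0; iy < ny; ++iy) tx.solve(wstar.data() + (size_t)iy * nx, 1);
    };
    half1(u, us, sys.lu, sys.fu, sys.du, tux);
    half1(v, vs, sys.lv, sys.fv, sys.dv, tvx);

    // half-step 2: implicit in y, explicit in x + reaction at (u*, v*)
    laplacian(us.data(), nx, ny, sys.du / (h * h), sys.lu.data());
    laplacian(vs.data(), nx, ny, sys.dv / (h * h), sys.lv.data());
    if (react)
      reaction_terms(model, alpha, beta, sigma, us.data(), vs.data(), n,
                     sys.fu.data(), sys.fv.data());
    auto half2 = [&](std::vector<double>& wstar, std::vector<double>& w,
                     const std::vector<double>& lap, const std::vector<double>& R,
                     double dcoef, Thomas& ty) {
      double dh2 = dcoef / (h * h);
      for (int iy = 0; iy < ny; ++iy) {
        size_t off = (size_t)iy * nx;
        const double* rs = wstar.data() + (iy > 0 ? off - nx : off + nx);
        const double* rn = wstar.data() + (iy < ny - 1 ? off + nx : off - nx);
        for (int ix = 0; ix < nx; ++ix) {
          size_t i = off + ix;
          double lyv = dh2 * (rs[ix] + rn[ix] - 2.0 * wstar[i]);
          double lx = lap[i] - lyv;
          w[i] = wstar[i] + hdt * (lx + R[i]);
        }
      }
      for (int ix = 0; ix < nx; ++ix) ty.solve(w.data() + ix, nx);
    };
    half2(us, u, sys.lu, sys.fu, sys.du, tuy);
    half2(vs, v, sys.lv, sys.fv, sys.dv, tvy);

    if (resized) setup(dt);
    t += step;

    if (anybad(u.data(), n) || anybad(v.data(), n)) {
      return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                          _["v"] = NumericVector(v.begin(), v.end()),
                          _["status"] = "blowup", _["time"] = t,
                          _["deriv_norm"] = NA_REAL);
    }

    if (t >= next_check - 1e-12 || t >= tau_end - 1e-12) {
      next_check += check_every;
      sys.rhs(u.data(), v.data(), ru.data(), rv.data());
      deriv = std::max(maxabs(ru.data(), n), maxabs(rv.data(), n));
      if (deriv < steady_tol) { status = "steady"; break; }
    }
  }

  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["status"] = status, _["time"] = t,
                      _["deriv_norm"] = deriv);
}

// Explicit adaptive Dormand-Prince 5(4) on the full method-of-lines system.
// Accurate but step-size limited by diffusion stiffness; used for short
// horizons and verification runs.
// [[Rcpp::export(name = ".rd_integrate_rk45_cpp")]]
List rd_integrate_rk45_cpp(NumericVector u0, NumericVector v0, int nx, int ny,
                           double h, int model, double alpha, double beta,
                           double delta, double sigma, double tau_end,
                           double abstol, double reltol, double steady_tol,
                           double check_every, bool react) {
  RDSystem sys(model, nx, ny, h, alpha, beta, delta, sigma, react);
  int n = sys.n, N = 2 * n;
  std::vector<double> y(N), ytmp(N), yerr(N), ynew(N);
  std::copy(u0.begin(), u0.end(), y.begin());
  std::copy(v0.begin(), v0.end(), y.begin() + n);
  std::vector<std::vector<double>> k(7, std::vector<double>(N));

  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double A[7][6] = {
      {0, 0, 0, 0, 0, 0},
      {1.0 / 5, 0, 0, 0, 0, 0},
      {3.0 / 40, 9.0 / 40, 0, 0, 0, 0},
      {44.0 / 45, -56.0 / 15, 32.0 / 9, 0, 0, 0},
      {19372.0 / 6561, -25360.0 / 2187, 64448.0 / 6561, -212.0 / 729, 0, 0},
      {9017.0 / 3168, -355.0 / 33, 46732.0 / 5247, 49.0 / 176, -5103.0 / 18656, 0},
      {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192, -2187.0 / 6784, 11.0 / 84}};
  static const double B5[7] = {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192,
                               -2187.0 / 6784, 11.0 / 84, 0};
  static const double B4[7] = {5179.0 / 57600, 0, 7571.0 / 16695, 393.0 / 640,
                               -92097.0 / 339200, 187.0 / 2100, 1.0 / 40};
  (void)c2; (void)c3; (void)c4; (void)c5;

  auto rhs = [&](const std::vector<double>& yy, std::vector<double>& out) {
    sys.rhs(yy.data(), yy.data() + n, out.data(), out.data() + n);
  };

  double t = 0.0;
  double dt = std::min(1e-3, tau_end);
  double next_check = check_every;
  std::string status = "tau_end_reached";
  double deriv = NA_REAL;
  rhs(y, k[0]);
  bool fsal = true;

  while (t < tau_end - 1e-12) {
    if (dt > tau_end - t) dt = tau_end - t;
    if (!fsal) rhs(y, k[0]);
    for (int s = 1; s < 7; ++s) {
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (int j = 0; j < s; ++j) acc += A[s][j] * k[j][i];
        ytmp[i] = y[i] + dt * acc;
      }
      rhs(ytmp, k[s]);
    }
    double errnorm = 0.0;
    for (int i = 0; i < N; ++i) {
      double y5 = 0.0, y4 = 0.0;
      for (int s = 0; s < 7; ++s) { y5 += B5[s] * k[s][i]; y4 += B4[s] * k[s][i]; }
      ynew[i] = y[i] + dt * y5;
      double sc = abstol + reltol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double e = dt * (y5 - y4) / sc;
      errnorm += e * e;
    }
    errnorm = std::sqrt(errnorm / N);
    if (!std::isfinite(errnorm)) { dt *= 0.25; fsal = false; continue; }
    if (errnorm <= 1.0) {
      t += dt;
      std::swap(y, ynew);
      std::copy(k[6].begin(), k[6].end(), k[0].begin()); // FSAL
      fsal = true;
      if (anybad(y.data(), N)) {
        status = "blowup";
        break;
      }
      if (t >= next_check - 1e-12 || t >= tau_end - 1e-12) {
        next_check += check_every;
        deriv = maxabs(k[0].data(), N);
        if (deriv < steady_tol) { status = "steady"; break; }
      }
    } else {
      fsal = false;
    }
    double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
    dt *= std::min(5.0, std::max(0.2, fac));
  }

  NumericVector uo(n), vo(n);
  std::copy(y.begin(), y.begin() + n, uo.begin());
  std::copy(y.begin() + n, y.end(), vo.begin());
  return List::create(_["u"] = uo, _["v"] = vo, _["status"] = status,
                      _["time"] = t, _["deriv_norm"] = deriv);
}
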