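// Compiled core: reaction-network right-hand side and a stiff
// linearly-implicit Rosenbrock(2,3) integrator with step storage for
// cubic-Hermite dense output on the R side.
//
// The network arrives as a flat list prepared by compile_network(): all
// indices 0-based, all rate constants already converted to the active time
// base (hours in vivo, seconds in vitro).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct CompiledNet {
  int n;
  arma::vec prod, kdeg;
  arma::ivec vk_dep;
  // reactions
  arma::ivec r_kind;           // 0 = mm_activation, 1 = complex_formation, 2 = first_order
  arma::ivec r_cat, r_subA, r_subB, r_prod;
  arma::vec r_kcat, r_km, r_k;
  arma::ivec r_vkor, r_xa;     // tags: warfarin-inhibited regeneration, Xa catalytic site
  // vitamin-K production coupling
  int idx_vk;
  double vk_ref, km_vk, hill_vk;
  bool has_vkdep;
  // drug action
  double imax, ic50, ki;
  // drug exposure: either a constant (closed in-vitro tube) or an oral
  // superposition forcing (in vivo)
  double c_warf_const, c_riva_const;
  bool pk_active;
  int pk_drug;                 // 1 = warfarin, 2 = rivaroxaban
  double pk_ke, pk_ka, pk_coef;
  arma::vec pk_dose_times;     // same time base as the integration
};

CompiledNet unpack(const List& net) {
  CompiledNet cn;
  cn.n = as<int>(net["n"]);
  cn.prod = as<arma::vec>(net["prod"]);
  cn.kdeg = as<arma::vec>(net["kdeg"]);
  cn.vk_dep = as<arma::ivec>(net["vk_dep"]);
  cn.r_kind = as<arma::ivec>(net["r_kind"]);
  cn.r_cat = as<arma::ivec>(net["r_cat"]);
  cn.r_subA = as<arma::ivec>(net["r_subA"]);
  cn.r_subB = as<arma::ivec>(net["r_subB"]);
  cn.r_prod = as<arma::ivec>(net["r_prod"]);
  cn.r_kcat = as<arma::vec>(net["r_kcat"]);
  cn.r_km = as<arma::vec>(net["r_km"]);
  cn.r_k = as<arma::vec>(net["r_k"]);
  cn.r_vkor = as<arma::ivec>(net["r_vkor"]);
  cn.r_xa = as<arma::ivec>(net["r_xa"]);
  cn.idx_vk = as<int>(net["idx_vk"]);
  cn.vk_ref = as<double>(net["vk_ref"]);
  cn.km_vk = as<double>(net["km_vk"]);
  cn.hill_vk = as<double>(net["hill_vk"]);
  cn.has_vkdep = as<bool>(net["has_vkdep"]);
  cn.imax = as<double>(net["imax"]);
  cn.ic50 = as<double>(net["ic50"]);
  cn.ki = as<double>(net["ki"]);
  cn.c_warf_const = as<double>(net["c_warf"]);
  cn.c_riva_const = as<double>(net["c_riva"]);
  cn.pk_active = as<bool>(net["pk_active"]);
  cn.pk_drug = as<int>(net["pk_drug"]);
  cn.pk_ke = as<double>(net["pk_ke"]);
  cn.pk_ka = as<double>(net["pk_ka"]);
  cn.pk_coef = as<double>(net["pk_coef"]);
  cn.pk_dose_times = as<arma::vec>(net["pk_dose_times"]);
  return cn;
}

// oral one-compartment superposition, first-order absorption
double pk_conc(const CompiledNet& cn, double t) {
  double c = 0.0;
  const double ke = cn.pk_ke, ka = cn.pk_ka;
  for (arma::uword i = 0; i < cn.pk_dose_times.n_elem; ++i) {
    double dt = t - cn.pk_dose_times[i];
    if (dt < 0) break; // dose times sorted ascending
    if (std::abs(ka - ke) > 1e-12 * ka) {
      c += cn.pk_coef * (std::exp(-ke * dt) - std::exp(-ka * dt));
    } else {
      // limiting form as ka -> ke (coef carries F*D*ka/V here)
      c += cn.pk_coef * dt * std::exp(-ke * dt);
    }
  }
  return c;
}

// production scaling by available vitamin K, normalised to the simulation's
// own drug-free reference so that the drug-free state is an exact fixed point
double vk_phi(const CompiledNet& cn, double vk) {
  if (vk < 0) vk = 0;
  double h = cn.hill_vk;
  double f = std::pow(vk, h) / (std::pow(cn.km_vk, h) + std::pow(vk, h));
  double f0 = std::pow(cn.vk_ref, h) / (std::pow(cn.km_vk, h) + std::pow(cn.vk_ref, h));
  return f / f0;
}

void rhs(const CompiledNet& cn, double t, const arma::vec& y, arma::vec& dy) {
  // reaction rates are evaluated on the non-negative part of the state;
  // first-order degradation acts on the raw state so tiny negative
  // excursions relax back to zero
  arma::vec yp = arma::clamp(y, 0.0, arma::datum::inf);

  double c_warf = cn.c_warf_const, c_riva = cn.c_riva_const;
  if (cn.pk_active) {
    double c = pk_conc(cn, t);
    if (cn.pk_drug == 1) c_warf = c; else c_riva = c;
  }
  double inh = (c_warf > 0) ? cn.imax * c_warf / (cn.ic50 + c_warf) : 0.0;
  double xa_scale = (c_riva > 0) ? 1.0 / (1.0 + c_riva / cn.ki) : 1.0;

  double phi = 1.0;
  if (cn.has_vkdep && cn.idx_vk >= 0) phi = vk_phi(cn, yp[cn.idx_vk]);

  for (int i = 0; i < cn.n; ++i) {
    double p = cn.prod[i];
    if (cn.vk_dep[i]) p *= phi;
    dy[i] = p - cn.kdeg[i] * y[i];
  }

  for (arma::uword r = 0; r < cn.r_kind.n_elem; ++r) {
    int kind = cn.r_kind[r];
    if (kind == 0) { // Michaelis-Menten activation
      double cat = yp[cn.r_cat[r]];
      double s = yp[cn.r_subA[r]];
      double kcat = cn.r_kcat[r];
      if (cn.r_xa[r]) kcat *= xa_scale;
      double v = kcat * cat * s / (cn.r_km[r] + s);
      dy[cn.r_subA[r]] -= v;
      dy[cn.r_prod[r]] += v;
    } else if (kind == 1) { // 1:1 complex formation, removes both partners
      double v = cn.r_k[r] * yp[cn.r_subA[r]] * yp[cn.r_subB[r]];
      dy[cn.r_subA[r]] -= v;
      dy[cn.r_subB[r]] -= v;
      dy[cn.r_prod[r]] += v;
    } else { // first order conversion
      double k = cn.r_k[r];
      if (cn.r_vkor[r]) k *= (1.0 - inh);
      double v = k * yp[cn.r_subA[r]];
      dy[cn.r_subA[r]] -= v;
      if (cn.r_prod[r] >= 0) dy[cn.r_prod[r]] += v;
    }
  }
}

void num_jacobian(const CompiledNet& cn, double t, const arma::vec& y,
                  const arma::vec& f0, arma::mat& J) {
  const int n = cn.n;
  arma::vec yp = y, fp(n);
  for (int j = 0; j < n; ++j) {
    double dy = std::sqrt(arma::datum::eps) * std::max(1e-5, std::abs(y[j]));
    yp[j] = y[j] + dy;
    rhs(cn, t, yp, fp);
    J.col(j) = (fp - f0) / dy;
    yp[j] = y[j];
  }
}

} // namespace

// [[Rcpp::export]]
arma::vec cpp_rhs(List net, double t, arma::vec y) {
  CompiledNet cn = unpack(net);
  if ((int)y.n_elem != cn.n) stop("state vector length %d does not match network size %d",
                                  (int)y.n_elem, cn.n);
  arma::vec dy(cn.n);
  rhs(cn, t, y, dy);
  return dy;
}

// [[Rcpp::export]]
double cpp_pk_conc(List net, double t) {
  CompiledNet cn = unpack(net);
  return pk_conc(cn, t);
}

// Rosenbrock(2,3) pair (the ode23s formulas) with numerical Jacobian per
// step. Returns every accepted step with its derivative so the caller can
// build a C1 cubic-Hermite interpolant.
// [[Rcpp::export]]
List cpp_simulate(List net, arma::vec y0, double t0, double t1,
                  double rtol, double atol, double hmax, int max_steps) {
  CompiledNet cn = unpack(net);
  const int n = cn.n;
  if ((int)y0.n_elem != n) stop("state vector length %d does not match network size %d",
                                (int)y0.n_elem, n);
  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);

  std::vector<double> ts;
  std::vector<arma::vec> ys, fs;

  arma::vec y = y0, f0(n), f1(n), f2(n), k1(n), k2(n), k3(n), err(n), Tt(n, arma::fill::zeros);
  double t = t0;
  rhs(cn, t, y, f0);
  ts.push_back(t); ys.push_back(y); fs.push_back(f0);

  double span = t1 - t0;
  if (span <= 0) stop("t1 must exceed t0");
  if (hmax <= 0) hmax = span;
  double h = std::min(hmax, span / 100.0);
  if (h <= 0) h = span * 1e-6;

  arma::mat J(n, n), W(n, n), I = arma::eye(n, n);
  int steps = 0;
  bool nonauto = cn.pk_active;

  while (t < t1) {
    if (steps++ > max_steps) {
      return List::create(_["ok"] = false, _["message"] = "max step count exceeded",
                          _["t_last"] = t,
                          _["t"] = NumericVector(ts.begin(), ts.end()));
    }
    h = std::min(h, t1 - t);
    num_jacobian(cn, t, y, f0, J);
    if (nonauto) {
      double dts = std::max(1e-8, 1e-8 * std::abs(t));
      arma::vec fshift(n);
      rhs(cn, t + dts, y, fshift);
      Tt = (fshift - f0) / dts;
    }

    bool accepted = false;
    while (!accepted) {
      W = I - (h * d) * J;
      arma::vec rhs1 = f0 + (h * d) * Tt;
      bool solved = arma::solve(k1, W, rhs1, arma::solve_opts::fast + arma::solve_opts::no_approx);
      if (!solved) { h *= 0.5; if (h < 1e-14 * span) {
          return List::create(_["ok"] = false, _["message"] = "singular Rosenbrock matrix",
                              _["t_last"] = t, _["t"] = NumericVector(ts.begin(), ts.end())); }
        continue; }
      rhs(cn, t + 0.5 * h, y + 0.5 * h * k1, f1);
      arma::vec rhs2 = f1 - k1;
      arma::vec tmp;
      arma::solve(tmp, W, rhs2, arma::solve_opts::fast + arma::solve_opts::no_approx);
      k2 = tmp + k1;
      arma::vec ynew = y + h * k2;
      rhs(cn, t + h, ynew, f2);
      arma::vec rhs3 = f2 - e32 * (k2 - f1) - 2.0 * (k1 - f0) + (h * d) * Tt;
      arma::solve(k3, W, rhs3, arma::solve_opts::fast + arma::solve_opts::no_approx);
      err = (h / 6.0) * (k1 - 2.0 * k2 + k3);

      double errnorm = 0.0;
      for (int i = 0; i < n; ++i) {
        double sc = atol + rtol * std::max(std::abs(y[i]), std::abs(ynew[i]));
        double e = err[i] / sc;
        errnorm += e * e;
      }
      errnorm = std::sqrt(errnorm / n);

      if (errnorm <= 1.0 || h <= 1e-13 * span) {
        t += h;
        y = ynew;
        f0 = f2;
        ts.push_back(t); ys.push_back(y); fs.push_back(f0);
        double fac = (errnorm > 0) ? 0.9 * std::pow(errnorm, -1.0 / 3.0) : 5.0;
        h = std::min(hmax, h * std::min(5.0, std::max(0.2, fac)));
        accepted = true;
      } else {
        double fac = 0.9 * std::pow(errnorm, -1.0 / 3.0);
        h *= std::min(0.5, std::max(0.1, fac));
        if (h < 1e-14 * span) {
          return List::create(_["ok"] = false, _["message"] = "step size underflow",
                              _["t_last"] = t, _["t"] = NumericVector(ts.begin(), ts.end()));
        }
      }
    }
  }

  const int m = (int)ts.size();
  arma::mat Y(m, n), F(m, n);
  for (int i = 0; i < m; ++i) { Y.row(i) = ys[i].t(); F.row(i) = fs[i].t(); }
  return List::create(_["ok"] = true,
                      _["t"] = NumericVector(ts.begin(), ts.end()),
                      _["y"] = Y, _["f"] = F);
}
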