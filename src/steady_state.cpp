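// Damped-Newton / pseudo-transient steady-state solver for the compiled
// network representation. Mirrors the rate arithmetic of evaluate_rates()
// on the R side (the two are cross-checked in the test suite).
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Net {
  int n, m;
  std::vector<int> kind;                 // 1..6, matching REACTION_KINDS order
  std::vector<int> r_ptr, r_idx;         // indices converted to 0-based
  std::vector<double> r_st;
  std::vector<int> p_ptr, p_idx;
  std::vector<double> p_st;
  std::vector<int> m_ptr, m_idx;
  std::vector<int> clamp_idx;            // 0-based, may be empty
};

std::vector<int> ivec(const List& cm, const char* nm, int shift = 0) {
  IntegerVector v = cm[nm];
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] + shift;
  return out;
}
std::vector<double> dvec(const List& cm, const char* nm) {
  NumericVector v = cm[nm];
  return std::vector<double>(v.begin(), v.end());
}

Net unpack(const List& cm) {
  Net net;
  net.n = as<int>(cm["n"]);
  net.kind = ivec(cm, "kind");
  net.m = (int)net.kind.size();
  net.r_ptr = ivec(cm, "r_ptr"); net.r_idx = ivec(cm, "r_idx", -1);
  net.r_st = dvec(cm, "r_st");
  net.p_ptr = ivec(cm, "p_ptr"); net.p_idx = ivec(cm, "p_idx", -1);
  net.p_st = dvec(cm, "p_st");
  net.m_ptr = ivec(cm, "m_ptr"); net.m_idx = ivec(cm, "m_idx", -1);
  net.clamp_idx = ivec(cm, "clamp_idx0");
  return net;
}

// residual f = dx/dt and (optionally) Jacobian J = df/dx
void rhs(const Net& net, const arma::vec& k, const arma::vec& Km,
         const arma::vec& deg, const arma::vec& x,
         arma::vec& f, arma::mat* J) {
  f = -deg % x;
  if (J) { J->zeros(); J->diag() = -deg; }

  for (int j = 0; j < net.m; ++j) {
    double M = 1.0;
    for (int t = net.m_ptr[j]; t < net.m_ptr[j + 1]; ++t) M *= x[net.m_idx[t]];
    int r0 = net.r_ptr[j], r1 = net.r_ptr[j + 1];
    double v = 0.0;
    // flux value
    switch (net.kind[j]) {
    case 1: v = k[j]; break;                       // synthesis
    case 2: v = k[j] * x[net.r_idx[r0]]; break;    // degradation
    case 3: {                                      // mass action activation
      double P = 1.0;
      for (int t = r0; t < r1; ++t) P *= std::pow(x[net.r_idx[t]], net.r_st[t]);
      v = k[j] * M * P; break; }
    case 4: {                                      // michaelis-menten
      double S = x[net.r_idx[r0]];
      v = k[j] * M * S / (Km[j] + S); break; }
    case 5: {                                      // complex formation
      double P = 1.0;
      for (int t = r0; t < r1; ++t) P *= std::pow(x[net.r_idx[t]], net.r_st[t]);
      v = k[j] * P; break; }
    case 6: v = k[j] * x[net.r_idx[r0]]; break;    // dissociation
    }
    for (int t = r0; t < r1; ++t) f[net.r_idx[t]] -= net.r_st[t] * v;
    for (int t = net.p_ptr[j]; t < net.p_ptr[j + 1]; ++t)
      f[net.p_idx[t]] += net.p_st[t] * v;

    if (!J) continue;
    // dv/dx for the species entering the flux
    auto add_dv = [&](int sp, double dv) {
      for (int t = r0; t < r1; ++t) (*J)(net.r_idx[t], sp) -= net.r_st[t] * dv;
      for (int t = net.p_ptr[j]; t < net.p_ptr[j + 1]; ++t)
        (*J)(net.p_idx[t], sp) += net.p_st[t] * dv;
    };
    switch (net.kind[j]) {
    case 1: break;
    case 2: case 6: add_dv(net.r_idx[r0], k[j]); break;
    case 3: case 5: {
      double kM = (net.kind[j] == 3) ? k[j] * M : k[j];
      // derivative w.r.t. each reactant
      for (int t = r0; t < r1; ++t) {
        double P = 1.0;
        for (int u = r0; u < r1; ++u) {
          double e = (u == t) ? net.r_st[u] - 1.0 : net.r_st[u];
          P *= std::pow(x[net.r_idx[u]], e);
        }
        add_dv(net.r_idx[t], kM * net.r_st[t] * P);
      }
      if (net.kind[j] == 3) {
        double P = 1.0;
        for (int u = r0; u < r1; ++u) P *= std::pow(x[net.r_idx[u]], net.r_st[u]);
        for (int t = net.m_ptr[j]; t < net.m_ptr[j + 1]; ++t) {
          double Mpart = 1.0;
          for (int u = net.m_ptr[j]; u < net.m_ptr[j + 1]; ++u)
            if (u != t) Mpart *= x[net.m_idx[u]];
          add_dv(net.m_idx[t], k[j] * Mpart * P);
        }
      }
      break; }
    case 4: {
      double S = x[net.r_idx[r0]];
      double den = Km[j] + S;
      add_dv(net.r_idx[r0], k[j] * M * Km[j] / (den * den));
      for (int t = net.m_ptr[j]; t < net.m_ptr[j + 1]; ++t) {
        double Mpart = 1.0;
        for (int u = net.m_ptr[j]; u < net.m_ptr[j + 1]; ++u)
          if (u != t) Mpart *= x[net.m_idx[u]];
        add_dv(net.m_idx[t], k[j] * Mpart * S / den);
      }
      break; }
    }
  }

  // clamped inputs: fixed state, zero rate
  for (size_t c = 0; c < net.clamp_idx.size(); ++c) {
    int i = net.clamp_idx[c];
    f[i] = 0.0;
    if (J) { J->row(i).zeros(); (*J)(i, i) = -1.0; }
  }
}

double resid_norm(const arma::vec& f, const arma::vec& x) {
  double r = 0.0;
  for (arma::uword i = 0; i < f.n_elem; ++i) {
    double v = std::fabs(f[i]) / (std::fabs(x[i]) + 1e-9);
    if (v > r) r = v;
  }
  return r;
}

// one solve; returns true on convergence
bool solve_one(const Net& net, const arma::vec& k, const arma::vec& Km,
               const arma::vec& deg, arma::vec& x, double tol,
               int max_newton, double& res_out) {
  arma::vec f(net.n);
  arma::mat J(net.n, net.n);

  // plain damped Newton from the warm start
  rhs(net, k, Km, deg, x, f, &J);
  double res = resid_norm(f, x);
  for (int it = 0; it < max_newton && res > tol; ++it) {
    arma::vec dx;
    if (!arma::solve(dx, J, -f, arma::solve_opts::no_approx)) break;
    double step = 1.0;
    bool ok = false;
    for (int h = 0; h < 10; ++h) {
      arma::vec xn = x + step * dx;
      xn.transform([](double v) { return v < 0.0 ? 0.0 : v; });
      arma::vec fn(net.n);
      rhs(net, k, Km, deg, xn, fn, nullptr);
      double rn = resid_norm(fn, xn);
      if (rn < res || rn < tol) { x = xn; res = rn; ok = true; break; }
      step *= 0.5;
    }
    if (!ok) break;
    rhs(net, k, Km, deg, x, f, &J);
    res = resid_norm(f, x);
  }

  if (res <= tol) { res_out = res; return true; }

  // pseudo-transient continuation fallback (implicit Euler with growing dt)
  double dt = 0.1;
  rhs(net, k, Km, deg, x, f, nullptr);
  res = resid_norm(f, x);
  for (int it = 0; it < 400 && res > tol; ++it) {
    rhs(net, k, Km, deg, x, f, &J);
    arma::mat A = arma::eye(net.n, net.n) / dt - J;
    arma::vec dx;
    if (!arma::solve(dx, A, f, arma::solve_opts::no_approx)) { dt *= 0.5; continue; }
    arma::vec xn = x + dx;
    xn.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    arma::vec fn(net.n);
    rhs(net, k, Km, deg, xn, fn, nullptr);
    double rn = resid_norm(fn, xn);
    if (rn <= res * 1.2 || rn < tol) { x = xn; res = rn; dt = std::min(dt * 2.0, 1e8); }
    else dt *= 0.5;
    if (dt < 1e-12) break;
  }
  res_out = res;
  return res <= tol;
}

} // namespace

// [[Rcpp::export(name = ".ss_solve")]]
List ss_solve(List cm, NumericVector k, NumericVector Km, NumericVector deg,
              NumericVector x0, double tol, int max_newton) {
  Net net = unpack(cm);
  arma::vec kk(k.begin(), k.size());
  arma::vec km(Km.begin(), Km.size());
  for (arma::uword i = 0; i < km.n_elem; ++i) if (!std::isfinite(km[i])) km[i] = 1.0;
  arma::vec dd(deg.begin(), deg.size());
  arma::vec x(x0.begin(), x0.size());
  double res = NA_REAL;
  bool conv = solve_one(net, kk, km, dd, x, tol, max_newton, res);
  return List::create(_["state"] = NumericVector(x.begin(), x.end()),
                      _["residual"] = res, _["converged"] = conv);
}

// Batch solver for Monte Carlo runs: Kmat/Kmmat are n_runs x n_reactions,
// Degmat is n_runs x n_species; every run warm-starts from x0.
// [[Rcpp::export(name = ".ss_solve_batch")]]
List ss_solve_batch(List cm, NumericMatrix Kmat, NumericMatrix Kmmat,
                    NumericMatrix Degmat, NumericVector x0, double tol,
                    int max_newton, IntegerVector readout_idx) {
  Net net = unpack(cm);
  int R = Kmat.nrow();
  arma::vec start(x0.begin(), x0.size());
  NumericMatrix readouts(R, readout_idx.size());
  LogicalVector conv(R);
  NumericVector resv(R);
  for (int r = 0; r < R; ++r) {
    arma::vec kk(net.m), km(net.m), dd(net.n);
    for (int j = 0; j < net.m; ++j) {
      kk[j] = Kmat(r, j);
      double v = Kmmat(r, j);
      km[j] = std::isfinite(v) ? v : 1.0;
    }
    for (int i = 0; i < net.n; ++i) dd[i] = Degmat(r, i);
    arma::vec x = start;
    double res = NA_REAL;
    conv[r] = solve_one(net, kk, km, dd, x, tol, max_newton, res);
    resv[r] = res;
    for (int q = 0; q < readout_idx.size(); ++q) readouts(r, q) = x[readout_idx[q]];
  }
  return List::create(_["readouts"] = readouts, _["converged"] = conv,
                      _["residual"] = resv);
}
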