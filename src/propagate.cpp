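// Exact propagation of the linear 3-compartment + effect-site system under
// piecewise-constant infusion.  State x = (A1, A2, A3, C4).  For a constant
// rate r over a step of length dt,
//   x(t+dt) = A(dt) x(t) + r b(dt)
// where A(dt) = expm(M dt) and b(dt) = int_0^dt expm(M s) e1 ds; both are the
// top blocks of the exponential of the augmented (affine) system
//   [[M, e1], [0, 0]]
// evaluated with unit rate.  A and b depend only on dt, so they are cached
// per call: control loops revisit a handful of step lengths thousands of
// times.  The augmented form also avoids solving M x = -b (M may be
// near-singular when k10 -> 0).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct StepCache {
  const mat& M;
  std::vector<double> dts;
  std::vector<mat> As;
  std::vector<vec> bs;
  explicit StepCache(const mat& M_) : M(M_) {}

  void fetch(double dt, mat& A, vec& b) {
    for (size_t i = 0; i < dts.size(); ++i) {
      if (std::fabs(dts[i] - dt) < 1e-13) { A = As[i]; b = bs[i]; return; }
    }
    mat aug(5, 5, fill::zeros);
    aug.submat(0, 0, 3, 3) = M;
    aug(0, 4) = 1.0;
    mat E = expmat(aug * dt);
    A = E.submat(0, 0, 3, 3);
    b = E.submat(0, 4, 3, 4);
    if (dts.size() < 128) { dts.push_back(dt); As.push_back(A); bs.push_back(b); }
  }

  vec step(const vec& x, double r, double dt) {
    if (dt <= 0.0) return x;
    mat A; vec b;
    fetch(dt, A, b);
    return A * x + r * b;
  }
};

} // namespace

// [[Rcpp::export]]
arma::mat cpp_pw_states(const arma::mat& M, const arma::vec& x0,
                        const arma::vec& bounds, const arma::vec& rates,
                        const arma::vec& times) {
  const unsigned int nseg = rates.n_elem;
  const unsigned int nt = times.n_elem;
  StepCache sc(M);
  mat out(4, nt);
  vec x = x0;
  unsigned int ti = 0;
  for (unsigned int s = 0; s < nseg; ++s) {
    double t0 = bounds(s), t1 = bounds(s + 1);
    double r = rates(s);
    while (ti < nt && times(ti) <= t1 + 1e-12) {
      if (times(ti) < t0 - 1e-12) { out.col(ti) = x; ++ti; continue; }
      out.col(ti) = sc.step(x, r, times(ti) - t0);
      ++ti;
    }
    x = sc.step(x, r, t1 - t0);
    if (ti >= nt && s + 1 < nseg) break;
  }
  // times beyond the last boundary: continue with zero infusion
  double tend = bounds(bounds.n_elem - 1);
  while (ti < nt) {
    out.col(ti) = sc.step(x, 0.0, times(ti) - tend);
    ++ti;
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_c1_at(const arma::mat& M, const arma::vec& x0,
                    const arma::vec& bounds, const arma::vec& rates,
                    const arma::vec& times, double V1) {
  mat st = cpp_pw_states(M, x0, bounds, rates, times);
  return st.row(0).t() / V1;
}

// Maximum future effect-site concentration: rate `r` applied on [0, t_on],
// zero thereafter, scanned to `horizon` on a fixed grid with parabolic
// refinement around the grid maximum.
// [[Rcpp::export]]
double cpp_peak_c4(const arma::mat& M, const arma::vec& x0, double r,
                   double t_on, double horizon, double dt) {
  StepCache sc(M);
  vec x = x0;
  double best = x(3);
  double prev1 = x(3), prev2 = NA_REAL;
  double best_prev1 = NA_REAL, best_next = NA_REAL;
  bool want_next = false;

  auto consider = [&](double c4) {
    if (want_next) { best_next = c4; want_next = false; }
    if (c4 > best) { best = c4; best_prev1 = prev1; want_next = true; }
    prev2 = prev1; prev1 = c4;
  };

  if (t_on > 0.0) {
    int n_on = std::max(1, (int)std::ceil(t_on / dt));
    double h = t_on / n_on;
    for (int i = 0; i < n_on; ++i) { x = sc.step(x, r, h); consider(x(3)); }
  }
  int n_off = std::max(1, (int)std::ceil((horizon - t_on) / dt));
  for (int i = 0; i < n_off; ++i) { x = sc.step(x, 0.0, dt); consider(x(3)); }

  if (std::isfinite(best_prev1) && std::isfinite(best_next)) {
    double a = best_prev1, b = best, c = best_next;
    double denom = a - 2.0 * b + c;
    if (denom < 0.0) {
      double delta = 0.5 * (a - c) / denom;
      if (std::fabs(delta) <= 1.0)
        best = b - 0.25 * (a - c) * delta;
    }
  }
  return best;
}
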